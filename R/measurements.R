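# Measurement workflow: variable reduction, log transform, isometric size and
# size correction. Raw caliper measurements arrive as a stage "raw" trait
# table and leave as stage "size_corrected" residual traits ready for the
# comparative statistics.

#' Build a variable-reduction schema
#'
#' A schema maps each output variable to a list of input variables and a
#' combinator: `"sum"` for serial structures measured segment by segment,
#' `"mean"` for repeated or bilaterally paired measurements, `"identity"` for
#' variables kept as-is. Every input may be consumed by at most one output.
#'
#' @param mapping named list; each element is `list(inputs = c(...), op = ...)`.
#' @return A `reduction_schema` object.
#' @export
reduction_schema <- function(mapping) {
  if (is.null(names(mapping)) || anyDuplicated(names(mapping)))
    stop("output variables must be uniquely named")
  ops <- vapply(mapping, function(m) m$op, character(1))
  if (!all(ops %in% c("sum", "mean", "identity")))
    stop("combinator must be one of sum, mean, identity")
  inputs <- unlist(lapply(mapping, function(m) m$inputs))
  if (anyDuplicated(inputs))
    stop("input variable consumed twice: ",
         paste(unique(inputs[duplicated(inputs)]), collapse = ", "))
  structure(mapping, class = "reduction_schema")
}

#' @export
print.reduction_schema <- function(x, ...) {
  n_in <- length(unlist(lapply(x, function(m) m$inputs)))
  cat(sprintf("Reduction schema: %d input -> %d output variables\n",
              n_in, length(x)))
  invisible(x)
}

#' Read or write a reduction schema as JSON
#'
#' The JSON is an object mapping output names to
#' `{"inputs": [...], "op": "sum"|"mean"|"identity"}`.
#'
#' @param path JSON file path.
#' @return `read_reduction_schema` returns a [reduction_schema()].
#' @export
read_reduction_schema <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  reduction_schema(lapply(raw, function(m)
    list(inputs = as.character(m$inputs), op = m$op)))
}

#' @rdname read_reduction_schema
#' @param schema a [reduction_schema()].
#' @export
write_reduction_schema <- function(schema, path) {
  jsonlite::write_json(lapply(unclass(schema), function(m)
    list(inputs = m$inputs, op = m$op)), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Default 70-to-36 measurement reduction schema
#'
#' Encodes the standard whole-body caliper protocol for scorpions reduced to
#' 36 analysis variables: for each of the four walking-leg pairs, trochanter
#' and femur lengths are summed into a proximal leg part and patella, tibia
#' and metatarsus lengths into a distal leg part (biomechanically functional
#' units); the five metasoma segment lengths are summed while their widths and
#' heights are averaged; ten pedipalp measurements are averaged between the
#' left and right appendage; fifteen prosoma, mesosoma and telson measurements
#' pass through unchanged. The concrete variable inventory is a synthetic
#' reconstruction of such a 70-measurement protocol (it is not a published
#' measurement table); supply your own schema via [read_reduction_schema()]
#' when your column names differ.
#'
#' @return A [reduction_schema()] with 70 inputs and 36 outputs.
#' @export
default_reduction_schema <- function() {
  mapping <- list()
  for (leg in c("I", "II", "III", "IV")) {
    mapping[[paste0("leg_", leg, "_proximal_length")]] <- list(
      inputs = paste0("leg_", leg, "_", c("trochanter", "femur"), "_length"),
      op = "sum")
    mapping[[paste0("leg_", leg, "_distal_length")]] <- list(
      inputs = paste0("leg_", leg, "_", c("patella", "tibia", "metatarsus"),
                      "_length"),
      op = "sum")
  }
  mapping$metasoma_length <- list(
    inputs = paste0("metasoma_segment", 1:5, "_length"), op = "sum")
  mapping$metasoma_width_avg <- list(
    inputs = paste0("metasoma_segment", 1:5, "_width"), op = "mean")
  mapping$metasoma_height_avg <- list(
    inputs = paste0("metasoma_segment", 1:5, "_height"), op = "mean")
  pedipalp_parts <- c("femur_length", "femur_width", "femur_height",
                      "patella_length", "patella_width", "chela_length",
                      "chela_width", "chela_height",
                      "movable_finger_length", "fixed_finger_length")
  for (part in pedipalp_parts) {
    mapping[[paste0("pedipalp_", part)]] <- list(
      inputs = paste0("pedipalp_", c("left", "right"), "_", part), op = "mean")
  }
  passthrough <- c("carapace_length", "carapace_anterior_width",
                   "carapace_posterior_width", "prosoma_height",
                   "mesosoma_length", "mesosoma_width", "sternum_length",
                   "sternum_width", "genital_operculum_length",
                   "pectine_length", "telson_length", "telson_height",
                   "vesicle_length", "vesicle_width", "aculeus_length")
  for (v in passthrough) mapping[[v]] <- list(inputs = v, op = "identity")
  reduction_schema(mapping)
}

#' Reduce raw measurements to analysis variables
#'
#' @param raw a stage `"raw"` [trait_table()].
#' @param schema a [reduction_schema()]; defaults to
#'   [default_reduction_schema()].
#' @return A stage `"reduced"` [trait_table()].
#' @export
reduce_variables <- function(raw, schema = default_reduction_schema()) {
  if (trait_stage(raw) != "raw") stop("reduce_variables expects a raw table")
  missing <- setdiff(unlist(lapply(schema, function(m) m$inputs)),
                     colnames(raw))
  if (length(missing) > 0)
    stop("schema references missing variables: ",
         paste(utils::head(missing, 8), collapse = ", "))
  x <- unclass(raw)
  out <- vapply(schema, function(m) {
    cols <- x[, m$inputs, drop = FALSE]
    switch(m$op,
           sum = rowSums(cols),
           mean = rowMeans(cols),
           identity = cols[, 1])
  }, numeric(nrow(x)))
  trait_table(out, species_ids = rownames(x),
              variable_names = names(schema), stage = "reduced")
}

#' Natural-log transform a reduced trait table
#'
#' @param t a stage `"reduced"` [trait_table()] with strictly positive values.
#' @return A stage `"log"` [trait_table()].
#' @export
log_transform <- function(t) {
  if (trait_stage(t) != "reduced") stop("log_transform expects a reduced table")
  if (any(t <= 0)) stop("all measurements must be positive for log transform")
  trait_table(log(unclass(t)), stage = "log")
}

#' Isometric body size
#'
#' Projects each species' log-measurement row onto the unit isometric vector
#' `(1/sqrt(p), ..., 1/sqrt(p))`, yielding a scalar size proxy that weights
#' every measurement equally. Doubling every raw measurement of a species adds
#' `log(2) * sqrt(p)` to its score.
#'
#' @param t a stage `"log"` [trait_table()].
#' @return Named numeric vector of per-species size scores.
#' @export
iso_size <- function(t) {
  if (trait_stage(t) != "log") stop("iso_size expects a log-stage table")
  p <- ncol(t)
  if (p == 0) stop("no variables")
  s <- rowSums(unclass(t)) / sqrt(p)
  names(s) <- rownames(t)
  s
}

#' Size-correct log traits against isometric size
#'
#' Replaces each variable with its residuals from an ordinary least-squares
#' regression (with intercept) on the size vector. Each output column has mean
#' zero and zero sample correlation with size; the operation is idempotent.
#' The regression is deliberately non-phylogenetic -- the phylogeny enters the
#' analysis only in the downstream GLS stages.
#'
#' @param t a stage `"log"` [trait_table()].
#' @param s size vector from [iso_size()] (default) or user-supplied, aligned
#'   to the table's species order.
#' @return A stage `"size_corrected"` [trait_table()].
#' @export
size_correct <- function(t, s = iso_size(t)) {
  if (!trait_stage(t) %in% c("log", "size_corrected"))
    stop("size_correct expects a log-stage table")
  if (length(s) != nrow(t)) stop("size vector length must match species count")
  if (stats::sd(s) == 0) stop("size vector is constant; regression undefined")
  X <- cbind(1, s)
  Y <- unclass(t)
  resid <- Y - X %*% solve(crossprod(X), crossprod(X, Y))
  trait_table(resid, species_ids = rownames(t),
              variable_names = colnames(t), stage = "size_corrected")
}
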