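# Design-matrix construction: turns a melsm_spec plus a long-format dataset
# into the fixed- and random-effect matrices of the two submodels.

#' Build design matrices for a MELSM specification
#'
#' @param data A long-format data frame with one row per encounter, an `id`
#'   column identifying subjects, and every covariate named by `spec`.
#' @param spec A [melsm_spec()].
#' @return A list of class `melsm_design` with elements `subject` (integer
#'   subject index per row), `subject_ids` (original labels), `X_loc`,
#'   `X_scale` (fixed-effect matrices), `Z_loc`, `Z_scale` (random-effect
#'   matrices with at most two columns: intercept then slope), and `y`
#'   (outcome vector, if a `y` column is present). Matrix columns are named;
#'   the fixed intercept column of ones comes first when present. Row order
#'   of `data` is preserved.
#' @export
build_design <- function(data, spec) {
  stopifnot(inherits(spec, "melsm_spec"), is.data.frame(data))
  if (nrow(data) == 0) abort("empty dataset: no rows to build a design from")
  if (!"id" %in% names(data)) abort("dataset must contain an 'id' column")
  subject <- match(data$id, unique(data$id))
  structure(
    list(
      subject = subject,
      subject_ids = unique(data$id),
      X_loc = fixed_matrix(data, spec$location),
      X_scale = fixed_matrix(data, spec$scale),
      Z_loc = random_matrix(data, spec$location$random),
      Z_scale = random_matrix(data, spec$scale$random),
      y = if ("y" %in% names(data)) data$y else NULL,
      spec = spec
    ),
    class = "melsm_design"
  )
}

fixed_matrix <- function(data, sub) {
  cols <- list()
  if (sub$intercept) cols[["(Intercept)"]] <- rep(1, nrow(data))
  if (nrow(sub$fixed_terms)) {
    labels <- term_labels(sub$fixed_terms)
    for (k in seq_len(nrow(sub$fixed_terms))) {
      nm <- sub$fixed_terms$covariate[k]
      if (!nm %in% names(data)) {
        abort(sprintf("covariate '%s' not found in the dataset", nm))
      }
      v <- data[[nm]]
      if (sub$fixed_terms$transform[k] == "sin") v <- sin(v)
      cols[[labels[k]]] <- v
    }
  }
  m <- do.call(cbind, cols)
  if (is.null(m)) m <- matrix(0, nrow(data), 0)
  m
}

random_matrix <- function(data, random) {
  if (is.null(random)) {
    return(matrix(0, nrow(data), 0))
  }
  cols <- list()
  if (random$intercept) cols[["(Intercept)"]] <- rep(1, nrow(data))
  if (!is.null(random$slope)) {
    if (!random$slope %in% names(data)) {
      abort(sprintf("covariate '%s' not found in the dataset", random$slope))
    }
    cols[[random$slope]] <- data[[random$slope]]
  }
  do.call(cbind, cols)
}
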