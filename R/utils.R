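#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

#' Derive independent child seeds from one master seed
#'
#' A single top-level seed is split deterministically into one seed per
#' stochastic sub-task, so that every stage of a run is reproducible from one
#' integer while stages remain statistically independent. The RNG state of the
#' caller is left untouched.
#'
#' @param seed integer master seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Run an expression under a fixed seed, restoring the caller's RNG state
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Content fingerprint for run reports: a vectorized polynomial hash over the
# serialized bytes. Not cryptographic; only used to detect that an input
# changed between runs.
fingerprint <- function(x) {
  r <- as.double(serialize(x, connection = NULL, version = 2))
  w <- (seq_along(r) %% 100003) + 1
  h <- (sum(r * w) + 257 * length(r)) %% 2147483647
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pz <- function(...) stop(sprintf(...), call. = FALSE)
warn_pz <- function(...) warning(sprintf(...), call. = FALSE)

GENE_CATEGORIES <- c("non_DE", "maize_specific", "teosinte_specific",
                     "shared_same", "shared_opposite")

#' Validate a count matrix
#'
#' Checks the invariants of the gene x sample count container: a numeric
#' matrix of nonnegative integers with unique, non-missing row (gene) and
#' column (sample) names.
#'
#' @param counts matrix to validate.
#' @return the matrix, invisibly, with storage mode coerced to integer-valued
#'   numeric.
#' @export
validate_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop_pz("counts must be a numeric matrix")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_pz("counts must have gene ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    stop_pz("duplicate gene ids: %s",
            paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                  collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) stop_pz("duplicate sample ids")
  if (anyNA(counts) || any(counts < 0)) {
    stop_pz("counts must be nonnegative and non-missing")
  }
  if (any(abs(counts - round(counts)) > 1e-9)) {
    bad <- which(abs(counts - round(counts)) > 1e-9, arr.ind = TRUE)[1, ]
    stop_pz("non-integer count at gene '%s', sample '%s'",
            rownames(counts)[bad[1]], colnames(counts)[bad[2]])
  }
  counts[] <- round(counts)
  invisible(counts)
}

#' Validate a sample-design table against a count matrix
#'
#' @param design data.frame with columns `sample_id`, `taxon`, `group`,
#'   `condition`.
#' @param counts optional count matrix whose sample ids must match exactly.
#' @return the design, invisibly.
#' @export
validate_sample_design <- function(design, counts = NULL) {
  need <- c("sample_id", "taxon", "group", "condition")
  if (!is.data.frame(design) || !all(need %in% names(design))) {
    stop_pz("design must be a data.frame with columns %s",
            paste(need, collapse = ", "))
  }
  if (anyDuplicated(design$sample_id)) stop_pz("duplicate sample ids in design")
  if (!all(design$condition %in% c("EH", "MA"))) {
    stop_pz("condition must be 'EH' or 'MA'")
  }
  if (anyNA(design[need])) stop_pz("design contains missing values")
  if (!is.null(counts)) {
    if (!setequal(design$sample_id, colnames(counts)) ||
        nrow(design) != ncol(counts)) {
      stop_pz("design sample ids do not match count matrix columns")
    }
  }
  invisible(design)
}
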