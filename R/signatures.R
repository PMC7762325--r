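#' The 96 trinucleotide substitution channels
#'
#' Fixed channel order: the six pyrimidine substitutions C>A, C>G, C>T, T>A,
#' T>C, T>G, each expanded over the 4 x 4 flanking bases in A, C, G, T order,
#' written as e.g. `A[C>A]A`.
#'
#' @return Character vector of length 96.
#' @export
sbs_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s)
    as.vector(t(outer(bases, bases, function(f, t3)
      paste0(f, "[", s, "]", t3))))))
}

validate_signature_matrix <- function(mat) {
  if (nrow(mat) != 96) stop("signature matrix must have 96 channel rows")
  if (any(mat < 0)) stop("signature matrix entries must be >= 0")
  sums <- colSums(mat)
  if (any(abs(sums - 1) > 1e-8))
    stop("signature columns must sum to 1 (got ",
         paste(signif(sums, 6), collapse = ", "), ")")
  invisible(mat)
}

#' Synthetic signature matrix
#'
#' Generates k well-separated synthetic signatures for testing: each signature
#' concentrates most of its mass on its own disjoint block of channels
#' (Dirichlet within the block plus a small uniform floor elsewhere), so
#' pairwise cosine similarity stays low. These are synthetic stand-ins, not
#' the published CNS signature catalog, which is external data.
#'
#' @param k Number of signatures (<= 8).
#' @param seed Integer seed.
#' @param floor_mass Probability mass spread uniformly outside the block.
#' @return 96 x k probability matrix with columns `SYN_A`, `SYN_B`, ...
#' @export
synthetic_signature_matrix <- function(k = 4, seed = 1, floor_mass = 0.05) {
  stopifnot(k >= 1, k <= 8)
  set.seed(seed)
  block <- floor(96 / k)
  mat <- matrix(floor_mass / (96 - block), nrow = 96, ncol = k)
  for (j in seq_len(k)) {
    idx <- ((j - 1) * block + 1):(j * block)
    w <- stats::rgamma(length(idx), shape = 0.5)
    mat[idx, j] <- (1 - floor_mass) * w / sum(w)
  }
  rownames(mat) <- sbs_channels()
  colnames(mat) <- paste0("SYN_", LETTERS[seq_len(k)])
  validate_signature_matrix(mat)
  mat
}

#' Simulate a 96-channel mutation catalog from a signature mixture
#'
#' Draws `n_mutations` channel assignments from the multinomial mixture
#' `signature_matrix %*% exposures`.
#'
#' @param exposures Named numeric vector of fractions summing to 1 (names must
#'   match columns of `signature_matrix`).
#' @param signature_matrix 96 x k probability matrix.
#' @param n_mutations Total mutation count (>= 0).
#' @param seed Optional integer seed; when NULL the current RNG stream is
#'   used.
#' @return Integer vector of 96 channel counts summing to `n_mutations`.
#' @export
simulate_catalog <- function(exposures, signature_matrix, n_mutations,
                             seed = NULL) {
  validate_signature_matrix(signature_matrix)
  if (abs(sum(exposures) - 1) > 1e-6)
    stop("configuration error: exposures must sum to 1")
  if (is.null(names(exposures)))
    names(exposures) <- colnames(signature_matrix)
  exposures <- exposures[colnames(signature_matrix)]
  if (anyNA(exposures)) stop("exposure names do not match signature columns")
  if (!is.null(seed)) set.seed(seed)
  p <- as.vector(signature_matrix %*% exposures)
  counts <- if (n_mutations == 0) integer(96) else
    as.integer(stats::rmultinom(1, n_mutations, p))
  names(counts) <- rownames(signature_matrix)
  counts
}

#' Refit a mutation catalog against a signature matrix
#'
#' Solves the non-negative least-squares problem
#' min || c/sum(c) - S e ||_2 subject to e >= 0, normalizes the solution to
#' fractions of its own sum, and applies the acceptance rule: only signatures
#' contributing at least `accept_min` (default 10%, inclusive) are accepted.
#'
#' @param catalog Integer vector of 96 channel counts (names optional but
#'   checked against the matrix when present).
#' @param signature_matrix 96 x k probability matrix.
#' @param accept_min Acceptance cutoff on the exposure fraction (inclusive).
#'   Default 0.10.
#' @return List: `exposures` (named fractions summing to 1), `accepted`
#'   (character vector of signature names with exposure >= `accept_min`),
#'   `residual` (Euclidean norm of the fit residual).
#' @export
refit <- function(catalog, signature_matrix, accept_min = 0.10) {
  validate_signature_matrix(signature_matrix)
  if (length(catalog) != 96) stop("catalog must have 96 channels")
  if (!is.null(names(catalog)) &&
      !identical(names(catalog), rownames(signature_matrix)))
    stop("schema error: catalog channels do not match the signature matrix")
  total <- sum(catalog)
  if (total <= 0) stop("all-zero catalog cannot be refit")
  target <- catalog / total
  fit <- pracma::lsqnonneg(signature_matrix, target)
  e <- fit$x
  if (sum(e) <= 0) stop("degenerate refit: all exposures zero")
  exposures <- stats::setNames(e / sum(e), colnames(signature_matrix))
  accepted <- names(exposures)[exposures >= accept_min]
  resid <- sqrt(sum((target - as.vector(signature_matrix %*% e))^2))
  list(exposures = exposures, accepted = accepted, residual = resid)
}

#' Refit every catalog of a cohort
#'
#' @param catalogs 96 x n matrix of counts (one column per sample).
#' @param signature_matrix 96 x k probability matrix.
#' @param accept_min Acceptance cutoff. Default 0.10.
#' @return Data frame: `sample`, one exposure column per signature, and
#'   `accepted` (comma-separated accepted signature names).
#' @export
refit_cohort <- function(catalogs, signature_matrix, accept_min = 0.10) {
  out <- lapply(colnames(catalogs), function(s) {
    r <- refit(catalogs[, s], signature_matrix, accept_min)
    cbind(data.frame(sample = s),
          as.data.frame(t(r$exposures)),
          data.frame(accepted = paste(r$accepted, collapse = ",")))
  })
  do.call(rbind, out)
}
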