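# Folded circular fingerprints (ECFP, bond diameter 4) and Tanimoto
# similarity. One representation is shared by the classifier features and
# the applicability-domain diagnostics.

#' Folded extended-connectivity fingerprints (diameter 4)
#'
#' Computes binary circular fingerprints with bond diameter 4 and folds them
#' to a fixed length by OR-ing vector halves.
#'
#' @param smiles character vector of SMILES (all must parse).
#' @param n_bits folded length; must divide the native 4096-bit vector
#'   (default 2048).
#' @return binary matrix, one row per molecule, `n_bits` columns.
#' @export
ecfp4 <- function(smiles, n_bits = 2048) {
  if (length(smiles) == 0) stop("no molecules to fingerprint", call. = FALSE)
  bad <- smiles[!is_valid_smiles(smiles)]
  if (length(bad) > 0) {
    stop("cannot parse structure: ", bad[1], call. = FALSE)
  }
  refs <- ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"),
                                 identity)
  fp <- suppressWarnings(ChemmineOB::fingerprint_OB(refs, "ECFP4"))
  if (is.null(dim(fp))) fp <- matrix(fp, nrow = 1)
  if (nrow(fp) != length(smiles)) {
    stop("fingerprint computation dropped molecules", call. = FALSE)
  }
  if (n_bits > ncol(fp) || ncol(fp) %% n_bits != 0) {
    stop("n_bits must divide ", ncol(fp), call. = FALSE)
  }
  while (ncol(fp) > n_bits) {
    h <- ncol(fp) / 2
    fp <- (fp[, 1:h, drop = FALSE] + fp[, (h + 1):(2 * h), drop = FALSE]) > 0
    storage.mode(fp) <- "numeric"
  }
  fp <- (fp > 0) * 1
  rownames(fp) <- NULL
  fp
}

#' Tanimoto similarity between fingerprint sets
#'
#' @param a,b binary fingerprint matrices (rows = molecules) with equal
#'   column counts.
#' @return `nrow(a)` x `nrow(b)` matrix of Tanimoto coefficients; pairs of
#'   all-zero fingerprints get similarity 0.
#' @export
tanimoto <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, nrow = 1)
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  stopifnot(ncol(a) == ncol(b))
  inter <- a %*% t(b)
  denom <- outer(rowSums(a), rowSums(b), "+") - inter
  sim <- ifelse(denom > 0, inter / denom, 0)
  unname(sim)
}
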