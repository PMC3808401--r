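# Genetics link: pairwise misclassification rates, Kimura two-parameter
# distances from aligned ND2 sequences, and a Mantel permutation test of
# the (negative) association between the two matrices.

#' Construct a labeled distance matrix
#'
#' @param m square numeric matrix, symmetric with zero diagonal.
#' @param labels unique row/column labels.
#' @return Object of class \code{fin_dist} (a labeled matrix).
#' @export
distance_matrix <- function(m, labels = rownames(m)) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (is.null(labels) || anyDuplicated(labels))
    stop("distance matrix needs unique labels")
  if (max(abs(m - t(m))) > 1e-9) stop("distance matrix must be symmetric")
  if (any(abs(diag(m)) > 1e-12)) stop("distance matrix diagonal must be zero")
  if (any(m < 0)) stop("distances must be non-negative")
  dimnames(m) <- list(labels, labels)
  structure(m, class = c("fin_dist", "matrix"))
}

#' Pairwise misclassification-rate matrix
#'
#' Symmetric pooled rate between classes i and j: confusions in both
#' directions divided by the combined number of predictions of the two
#' classes, \eqn{(c_{ij} + c_{ji}) / (N_i + N_j)}, with zero diagonal.
#' Classes confused often get a large "distance" in classifier space.
#'
#' @param cm a \code{\link{confusion_matrix}} result.
#' @return A \code{\link{distance_matrix}} over the class labels.
#' @export
misclassification_matrix <- function(cm) {
  stopifnot(inherits(cm, "fin_confusion"))
  counts <- cm$counts
  tot <- cm$sums
  if (any(tot == 0)) stop("class with zero predictions")
  k <- nrow(counts)
  m <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    m[i, j] <- (counts[i, j] + counts[j, i]) / (tot[i] + tot[j])
  }
  distance_matrix(m, labels = rownames(counts))
}

# strip non-ACGT columns pairwise, return cleaned character matrices
.pairwise_clean <- function(a, b) {
  a <- toupper(unlist(strsplit(paste(a, collapse = ""), "")))
  b <- toupper(unlist(strsplit(paste(b, collapse = ""), "")))
  if (length(a) != length(b)) stop("sequences must be aligned (equal length)")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  list(a = a[ok], b = b[ok])
}

#' Kimura two-parameter distance between two aligned sequences
#'
#' \eqn{d = -\frac{1}{2}\ln(1 - 2P - Q) - \frac{1}{4}\ln(1 - 2Q)} with
#' transition proportion P and transversion proportion Q over the
#' pairwise-comparable sites (gap/ambiguity columns removed pairwise).
#' Computed through \code{ape::dist.dna(model = "K80", pairwise.deletion =
#' TRUE)}.
#'
#' @param seq_a,seq_b aligned DNA sequences (character strings or character
#'   vectors of bases).
#' @return Distance in substitutions per site.
#' @export
k2p_distance <- function(seq_a, seq_b) {
  cl <- .pairwise_clean(seq_a, seq_b)
  if (length(cl$a) == 0L) stop("zero comparable sites")
  dna <- ape::as.DNAbin(rbind(a = cl$a, b = cl$b))
  d <- suppressWarnings(
    as.numeric(ape::dist.dna(dna, model = "K80", pairwise.deletion = TRUE)))
  if (!is.finite(d)) stop("saturated")
  d
}

#' K2P distance matrix for a set of aligned sequences
#'
#' @param seqs named list/vector of aligned sequences, or a path to an
#'   aligned FASTA file (read with \code{ape::read.FASTA}).
#' @return A \code{\link{distance_matrix}} in substitutions per site.
#' @export
k2p_matrix <- function(seqs) {
  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs)) {
    dna <- ape::read.FASTA(seqs)
    seqs <- vapply(as.character(dna), paste, character(1), collapse = "")
  }
  labels <- names(seqs)
  if (is.null(labels)) stop("sequences must be named")
  k <- length(seqs)
  m <- matrix(0, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    m[i, j] <- m[j, i] <- k2p_distance(seqs[[i]], seqs[[j]])
  }
  distance_matrix(m, labels = labels)
}

#' Mantel permutation test between two distance matrices
#'
#' Pearson correlation r over the m(m-1)/2 upper-triangle pairs, with a
#' one-tailed permutation p-value obtained by jointly permuting the rows and
#' columns of the second matrix. The default alternative is
#' \code{"negative"} (smaller genetic distance associated with higher
#' misclassification), the direction of the study hypothesis; p is
#' \eqn{(\#\{r_{perm} \le r_{obs}\} + 1) / (n_{perm} + 1)} (mirrored for the
#' positive tail).
#'
#' @param a,b \code{\link{distance_matrix}} objects with identical labels in
#'   identical order.
#' @param n_perm number of permutations (default 9999).
#' @param seed permutation seed.
#' @param alternative \code{"negative"} (default) or \code{"positive"}.
#' @return List with \code{r}, \code{p}, \code{n_perm}, \code{alternative}.
#' @export
mantel_test <- function(a, b, n_perm = 9999L, seed = 1L,
                        alternative = c("negative", "positive")) {
  alternative <- match.arg(alternative)
  if (!identical(rownames(a), rownames(b)))
    stop("distance matrices must share labels and order")
  m <- nrow(a)
  if (m < 4L) stop("need at least 4 labels for a Mantel test")
  ut <- upper.tri(a)
  va <- a[ut]
  if (stats::sd(va) == 0 || stats::sd(b[ut]) == 0)
    stop("zero variance among off-diagonal distances")
  r_obs <- stats::cor(va, b[ut])
  set.seed(seed)
  hits <- 0L
  bm <- unclass(b)
  for (k in seq_len(n_perm)) {
    p <- sample.int(m)
    r_perm <- stats::cor(va, bm[p, p][ut])
    if (alternative == "negative") {
      if (r_perm <= r_obs) hits <- hits + 1L
    } else if (r_perm >= r_obs) hits <- hits + 1L
  }
  list(r = r_obs, p = (hits + 1) / (n_perm + 1),
       n_perm = as.integer(n_perm), alternative = alternative)
}

#' Read a distance matrix from CSV
#'
#' Square CSV with labels in the first column and header row.
#'
#' @param path CSV path.
#' @return A \code{\link{distance_matrix}}.
#' @export
read_distance_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  distance_matrix(as.matrix(df), labels = rownames(df))
}

#' Write a distance matrix to CSV
#'
#' @param d a \code{\link{distance_matrix}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_distance_csv <- function(d, path) {
  utils::write.csv(as.data.frame(unclass(d)), path)
  invisible(path)
}
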