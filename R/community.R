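#' Construct a genome x sample relative-abundance matrix
#'
#' Columns (samples) are renormalized to sum to one on load; negative
#' entries are an error.  Rows are genomes, matched to auxotrophy profiles
#' and phylogeny leaves by rowname.
#'
#' @param p numeric matrix, genomes in rows, samples in columns, with
#'   dimnames.
#' @return matrix of class `community_abundance`.
#' @export
abundance_matrix <- function(p) {
  p <- as.matrix(p)
  if (is.null(rownames(p)) || is.null(colnames(p)))
    stop("abundance matrix needs genome rownames and sample colnames")
  if (any(p < 0)) stop("negative abundances")
  cs <- colSums(p)
  if (any(cs <= 0)) stop("sample(s) with zero total abundance: ",
                         paste(colnames(p)[cs <= 0], collapse = ", "))
  p <- sweep(p, 2, cs, "/")
  structure(p, class = c("community_abundance", "matrix"))
}

#' Read / write an abundance matrix as TSV (genomes x samples)
#' @param path file path.
#' @return a `community_abundance` matrix.
#' @export
read_abundance <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                    check.names = FALSE)
  abundance_matrix(as.matrix(tab))
}

#' @rdname read_abundance
#' @param p a `community_abundance` matrix.
#' @export
write_abundance <- function(p, path) {
  write.table(data.frame(genome_id = rownames(p), p, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

check_profiles_cover <- function(p, B, presence_threshold = 0) {
  abundant <- rownames(p)[rowSums(p > presence_threshold) > 0]
  missing <- setdiff(abundant, rownames(B))
  if (length(missing))
    stop("abundant genome(s) without auxotrophy profile: ",
         paste(missing, collapse = ", "))
}

#' Relative auxotrophy abundance per sample and amino acid
#'
#' For sample `j` and amino acid `k`, the summed relative abundance of
#' genomes auxotrophic for `k`:  `y_jk = sum_i p_ij * b_ik`, a value in
#' `[0, 1]`.  Every genome with positive abundance must carry a profile;
#' silently dropping unprofiled genomes would shift the denominator.
#'
#' @param p a `community_abundance` matrix.
#' @param profiles profile table from [profiles_table()].
#' @return samples x amino-acids matrix of `y_jk`.
#' @export
auxotrophy_frequency <- function(p, profiles) {
  B <- profile_matrix(profiles)
  check_profiles_cover(p, B)
  keep <- intersect(rownames(p), rownames(B))
  t(p[keep, , drop = FALSE]) %*% B[keep, , drop = FALSE]
}

#' Abundance-weighted average number of auxotrophies per sample
#'
#' `y_j = sum_i a_i * p_ij`, where `a_i` is genome `i`'s auxotrophy count;
#' a value in `[0, 20]` equal to the row sum of [auxotrophy_frequency()].
#'
#' @inheritParams auxotrophy_frequency
#' @return named numeric vector over samples.
#' @export
weighted_auxotrophy_count <- function(p, profiles) {
  B <- profile_matrix(profiles)
  check_profiles_cover(p, B)
  a <- setNames(rowSums(B), rownames(B))
  keep <- intersect(rownames(p), names(a))
  as.numeric(t(p[keep, , drop = FALSE]) %*% a[keep]) |>
    setNames(colnames(p))
}

#' Mean pairwise Hamming distance of co-occurring auxotrophy profiles
#'
#' The Hamming distance between two profiles is the number of amino acids
#' on which their auxotrophy calls differ (0..20).  Per sample, the
#' unweighted mean over all unordered pairs of present genomes (abundance
#' above `presence_threshold`) summarizes the metabolic dissimilarity of
#' the community, an indicator of potential amino-acid cross-feeding.
#' Samples with fewer than two present genomes get `NA`.
#'
#' @inheritParams auxotrophy_frequency
#' @param presence_threshold abundance above which a genome counts as
#'   present; default 0 (any positive abundance).
#' @return named numeric vector over samples (NA where undefined).
#' @export
mean_pairwise_hamming <- function(p, profiles, presence_threshold = 0) {
  B <- profile_matrix(profiles)
  check_profiles_cover(p, B, presence_threshold)
  vapply(colnames(p), function(j) {
    present <- rownames(p)[p[, j] > presence_threshold]
    if (length(present) < 2) return(NA_real_)
    Bp <- B[present, , drop = FALSE]
    # disagreement counts for all pairs at once
    D <- Bp %*% t(1 - Bp) + (1 - Bp) %*% t(Bp)
    mean(D[upper.tri(D)])
  }, 0.0)
}

#' Shannon diversity per sample
#'
#' `H = -sum(p_i * ln(p_i))` over positive relative abundances, in nats
#' (natural logarithm), computed with vegan.
#'
#' @param p a `community_abundance` matrix (or one column).
#' @return named numeric vector of Shannon indices.
#' @export
shannon_index <- function(p) {
  p <- as.matrix(p)
  if (any(colSums(p) <= 0)) stop("all-zero abundance column")
  if (nrow(p) == 1)  # single taxon: H = 0 by definition
    return(setNames(rep(0, ncol(p)), colnames(p)))
  vegan::diversity(t(p), index = "shannon")
}

#' Per-sample community summary
#'
#' Bundles the per-sample community statistics: the abundance-weighted
#' auxotrophy count `y_j`, the mean pairwise Hamming distance, and the
#' Shannon index, one row per sample.
#'
#' @inheritParams mean_pairwise_hamming
#' @return data.frame: `sample_id`, `weighted_auxotrophy_count`,
#'   `mean_hamming`, `shannon`.
#' @export
community_summary <- function(p, profiles, presence_threshold = 0) {
  data.frame(
    sample_id = colnames(p),
    weighted_auxotrophy_count = weighted_auxotrophy_count(p, profiles),
    mean_hamming = mean_pairwise_hamming(p, profiles, presence_threshold),
    shannon = shannon_index(p),
    row.names = NULL, stringsAsFactors = FALSE)
}
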