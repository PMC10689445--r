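#' Read a genome phylogeny from Newick
#'
#' Wraps ape's Newick parser and enforces the invariants the UniFrac
#' computation needs: unique leaf labels and nonnegative branch lengths.
#' Edges without branch lengths default to 0 with a warning.
#'
#' @param source file path or Newick string.
#' @return an `ape::phylo` tree.
#' @export
read_newick <- function(source) {
  tree <- if (file.exists(source)) ape::read.tree(source)
          else ape::read.tree(text = source)
  if (is.null(tree)) stop("failed to parse Newick input")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; defaulting to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning("missing branch length(s) defaulted to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop("negative branch length(s)")
  tree
}

# per-edge abundance mass under the child node, for each input column
edge_masses <- function(tree, amat) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  post <- ape::reorder.phylo(tree, "postorder")
  masses <- matrix(0, nrow = nnode, ncol = ncol(amat))
  masses[seq_len(ntip), ] <- amat[tree$tip.label, , drop = FALSE]
  for (e in seq_len(nrow(post$edge))) {
    parent <- post$edge[e, 1]; child <- post$edge[e, 2]
    masses[parent, ] <- masses[parent, ] + masses[child, ]
  }
  # mass under each edge = mass of its child node, in post$edge order
  list(edge = post$edge, length = post$edge.length,
       mass = masses[post$edge[, 2], , drop = FALSE])
}

#' UniFrac distance between two communities on a genome phylogeny
#'
#' Unweighted UniFrac is the branch length unique to one community's leaf
#' set divided by the branch length spanned by either; the
#' weighted-normalized variant replaces presence by abundance mass:
#' `sum(len * |A - B|) / sum(len * (A + B))`, where `A`, `B` are the
#' relative-abundance masses under each branch.  Both are in `[0, 1]`,
#' symmetric, and invariant to rescaling all branch lengths.  Unrooted
#' input trees are midpoint-rooted first for determinism.
#'
#' @param tree phylogeny covering all positive-abundance genomes (error
#'   listing the missing ones otherwise).
#' @param a,b named relative-abundance vectors (renormalized to sum 1).
#' @param variant `"weighted_normalized"` (default; the analysis weights
#'   by relative abundances) or `"unweighted"`.
#' @return the distance, a scalar in `[0, 1]`.
#' @export
unifrac <- function(tree, a, b,
                    variant = c("weighted_normalized", "unweighted")) {
  variant <- match.arg(variant)
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  for (v in list(a, b)) {
    pos <- names(v)[v > 0]
    missing <- setdiff(pos, tree$tip.label)
    if (length(missing))
      stop("genome(s) absent from tree: ", paste(missing, collapse = ", "))
  }
  amat <- matrix(0, nrow = length(tree$tip.label), ncol = 2,
                 dimnames = list(tree$tip.label, c("a", "b")))
  amat[intersect(names(a), rownames(amat)), "a"] <-
    a[intersect(names(a), rownames(amat))]
  amat[intersect(names(b), rownames(amat)), "b"] <-
    b[intersect(names(b), rownames(amat))]
  if (sum(amat[, 1]) <= 0 || sum(amat[, 2]) <= 0)
    stop("each community needs positive total abundance")
  amat <- sweep(amat, 2, colSums(amat), "/")

  em <- edge_masses(tree, amat)
  A <- em$mass[, 1]; B <- em$mass[, 2]; len <- em$length
  if (variant == "unweighted") {
    ina <- A > 0; inb <- B > 0
    den <- sum(len[ina | inb])
    if (den == 0) return(0)
    sum(len[xor(ina, inb)]) / den
  } else {
    den <- sum(len * (A + B))
    if (den == 0) return(0)
    sum(len * abs(A - B)) / den
  }
}

#' Longitudinal stability records (1 - UniFrac per subject)
#'
#' Stability is one minus the UniFrac distance between a subject's two
#' time points, a value in `[0, 1]` where 1 means an unchanged community.
#' Subjects whose samples are missing from the abundance matrix are
#' skipped with a warning.
#'
#' @param tree genome phylogeny.
#' @param p a `community_abundance` matrix holding both time points.
#' @param manifest data.frame: `subject_id`, `sample_t1`, `sample_t2`.
#' @param variant UniFrac variant, see [unifrac()].
#' @return data.frame: `subject_id`, `sample_t1`, `sample_t2`, `unifrac`,
#'   `stability`.
#' @export
stability_records <- function(tree, p, manifest,
                              variant = "weighted_normalized") {
  stopifnot(all(c("subject_id", "sample_t1", "sample_t2") %in%
                  names(manifest)))
  ok <- manifest$sample_t1 %in% colnames(p) &
    manifest$sample_t2 %in% colnames(p)
  if (any(!ok))
    warning("subject(s) with missing sample(s) skipped: ",
            paste(manifest$subject_id[!ok], collapse = ", "))
  manifest <- manifest[ok, , drop = FALSE]
  u <- vapply(seq_len(nrow(manifest)), function(i)
    unifrac(tree, p[, manifest$sample_t1[i]], p[, manifest$sample_t2[i]],
            variant = variant), 0.0)
  data.frame(subject_id = manifest$subject_id,
             sample_t1 = manifest$sample_t1,
             sample_t2 = manifest$sample_t2,
             unifrac = u, stability = 1 - u,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Correlate microbiome stability with first-time-point auxotrophy load
#'
#' Spearman correlations between per-subject stability (1 - UniFrac) and,
#' at the first time point: (i) the abundance-weighted auxotrophy count
#' `y_j`, (ii) the mean pairwise Hamming distance, and (iii) each amino
#' acid's auxotrophy frequency `y_jk` (BH-corrected within the
#' per-amino-acid family).  When stability is constant across subjects the
#' correlations are undefined and reported as `NA`.
#'
#' @inheritParams stability_records
#' @param profiles profile table from [profiles_table()].
#' @param presence_threshold passed to [mean_pairwise_hamming()].
#' @return list with `records` (see [stability_records()]) and
#'   `associations` (long data.frame: `family`, `label_x`, `label_y`,
#'   `estimate`, `p_raw`, `p_adjusted`, `n`).
#' @export
stability_analysis <- function(tree, p, manifest, profiles,
                               variant = "weighted_normalized",
                               presence_threshold = 0) {
  rec <- stability_records(tree, p, manifest, variant)
  if (!nrow(rec)) stop("no paired subjects")
  p1 <- p[, rec$sample_t1, drop = FALSE]
  yj <- weighted_auxotrophy_count(p1, profiles)
  hm <- mean_pairwise_hamming(p1, profiles, presence_threshold)
  yjk <- auxotrophy_frequency(p1, profiles)

  one <- function(x, label, fam) {
    res <- tryCatch(suppressWarnings(partial_spearman(x, rec$stability)),
                    error = function(e)
                      list(rho = NA_real_, p = NA_real_,
                           n = sum(complete.cases(x, rec$stability))))
    data.frame(family = fam, label_x = label, label_y = "stability",
               estimate = res$rho, p_raw = res$p, n = res$n,
               stringsAsFactors = FALSE)
  }
  head_rows <- rbind(
    one(yj, "weighted_auxotrophy_count", "stability_headline"),
    one(hm, "mean_hamming", "stability_headline"))
  aa_rows <- do.call(rbind, lapply(colnames(yjk), function(aa)
    one(yjk[, aa], aa, "stability_aa")))

  head_rows$p_adjusted <- head_rows$p_raw  # headline tests stand alone
  aa_rows$p_adjusted <- bh_adjust(aa_rows$p_raw)
  list(records = rec, associations = rbind(head_rows, aa_rows))
}
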