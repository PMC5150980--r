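#' Bray-Curtis dissimilarity matrix
#'
#' For abundance profiles x, y: `d(x, y) = sum|x_i - y_i| / sum(x_i + y_i)`.
#' Symmetric, zero on the diagonal, bounded in [0, 1] for non-negative
#' inputs (1 = taxonomically disjoint samples).
#'
#' @param mat samples x taxa matrix (or data.frame) of non-negative counts
#'   or relative abundances; rows are samples.
#' @param relative convert each row to relative abundance before computing
#'   (the normalization used ahead of community ANOSIM); default `FALSE`.
#' @return symmetric dissimilarity matrix with the sample names of `mat`.
#' @export
bray_curtis <- function(mat, relative = FALSE) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("abundances must be non-negative")
  rs <- rowSums(mat)
  if (any(rs == 0)) {
    bad <- rownames(mat)[rs == 0]
    if (is.null(bad)) bad <- which(rs == 0)
    stop("all-zero sample(s): ", paste(bad, collapse = ", "))
  }
  if (relative) mat <- mat / rs
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      num <- sum(abs(mat[i, ] - mat[j, ]))
      den <- sum(mat[i, ] + mat[j, ])
      d[i, j] <- d[j, i] <- num / den
    }
  }
  d
}

anosim_R <- function(rank_d, within) {
  M <- length(rank_d)
  r_b <- mean(rank_d[!within])
  r_w <- mean(rank_d[within])
  # Clarke's divisor n(n-1)/4 = M/2, which makes R = 1 under perfect
  # separation and bounds R in [-1, 1]
  (r_b - r_w) / (M / 2)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based test of whether between-group dissimilarities exceed
#' within-group dissimilarities. All n(n-1)/2 pairwise dissimilarities are
#' ranked (ties get average ranks) and
#' `R = (mean between-group rank - mean within-group rank) / (n(n-1)/4)`,
#' so R is 1 when all between-group pairs are more dissimilar than every
#' within-group pair, and near 0 under the null. Significance comes from
#' permuting the group labels: `p = (#{R* >= R} + 1) / (n_permutations + 1)`,
#' or from exhaustive enumeration of all distinct label assignments when
#' `exact = TRUE` (p is then the exact proportion with R* >= R, the
#' identity assignment included).
#'
#' @param dissim square dissimilarity matrix (e.g. from [bray_curtis()]) or
#'   a `dist` object.
#' @param labels group label per sample; >= 2 groups, each with >= 2
#'   samples.
#' @param n_permutations number of random label permutations (>= 99;
#'   default 999).
#' @param seed integer seed for the permutations.
#' @param exact enumerate all distinct label assignments instead of
#'   sampling (feasible for small n).
#' @return object of class `anosim_result`: `R`, `p`, `n_permutations`,
#'   `seed`, `r_between`, `r_within`, `M`.
#' @export
anosim <- function(dissim, labels, n_permutations = 999, seed = NA_integer_,
                   exact = FALSE) {
  d <- as.matrix(dissim)
  n <- nrow(d)
  labels <- as.character(labels)
  if (length(labels) != n) stop("labels must match the number of samples")
  cnt <- table(labels)
  if (length(cnt) < 2) stop("ANOSIM needs >= 2 groups")
  if (any(cnt < 2))
    stop("every group needs >= 2 samples (offending: ",
         paste(names(cnt)[cnt < 2], collapse = ", "), ")")
  if (!exact && n_permutations < 99) stop("n_permutations must be >= 99")
  lower <- lower.tri(d)
  rank_d <- rank(d[lower])          # average ranks on ties
  pair_i <- row(d)[lower]; pair_j <- col(d)[lower]
  within_for <- function(lab) lab[pair_i] == lab[pair_j]
  obs <- anosim_R(rank_d, within_for(labels))
  if (exact) {
    perms <- multiset_permutations(labels)
    stats_all <- vapply(perms, function(lab) anosim_R(rank_d, within_for(lab)),
                        numeric(1))
    p <- mean(stats_all >= obs - 1e-12)
    n_perm <- length(perms)
  } else {
    if (!is.na(seed)) set.seed(as.integer(seed))
    stats_all <- replicate(n_permutations,
                           anosim_R(rank_d, within_for(sample(labels))))
    p <- (sum(stats_all >= obs - 1e-12) + 1) / (n_permutations + 1)
    n_perm <- n_permutations
  }
  structure(list(R = obs, p = p, n_permutations = n_perm,
                 seed = seed, exact = exact,
                 r_between = mean(rank_d[!within_for(labels)]),
                 r_within = mean(rank_d[within_for(labels)]),
                 M = length(rank_d),
                 permuted_R = stats_all),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.3f, P = %.4g (%s%d permutations)\n",
              x$R, x$p, if (x$exact) "exhaustive, " else "", x$n_permutations))
  invisible(x)
}

# all distinct orderings of a label multiset (group assignments)
multiset_permutations <- function(labels) {
  uniq <- sort(unique(labels))
  counts <- as.integer(table(factor(labels, levels = uniq)))
  names(counts) <- uniq
  out <- list()
  recurse <- function(prefix, remaining) {
    if (sum(remaining) == 0L) {
      out[[length(out) + 1]] <<- prefix
      return(invisible(NULL))
    }
    for (u in uniq) {
      if (remaining[[u]] > 0L) {
        rem <- remaining; rem[[u]] <- rem[[u]] - 1L
        recurse(c(prefix, u), rem)
      }
    }
  }
  recurse(character(0), counts)
  out
}

#' Read a community matrix with group labels from TSV
#'
#' Expected layout: first column `sample`, second column `group`, remaining
#' columns taxon counts.
#'
#' @param path TSV file path.
#' @return list with `counts` (samples x taxa matrix) and `groups`
#'   (character vector).
#' @export
read_community_matrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 4 || names(tab)[1] != "sample" || names(tab)[2] != "group")
    stop("community TSV must start with columns 'sample', 'group' ",
         "followed by taxon counts")
  counts <- as.matrix(tab[, -(1:2), drop = FALSE])
  rownames(counts) <- tab$sample
  storage.mode(counts) <- "double"
  list(counts = counts, groups = tab$group)
}
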