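#' Condition-median, z-scored expression profiles
#'
#' For each gene, the median across replicates is taken at every sampling
#' point (in the column order given by `design$condition` levels), then the
#' profile is z-scored across sampling points. Genes with zero variance
#' across points are dropped with a warning.
#'
#' @param mat Transformed matrix, genes x samples.
#' @param design data.frame with `sample` and `condition` columns covering
#'   the columns of `mat`; `condition` may be a factor to fix the point
#'   order (default: order of first appearance).
#' @return Genes x sampling-points matrix of standardised profiles.
#' @export
standardize_profiles <- function(mat, design) {
  mat <- as.matrix(mat)
  stopifnot(all(colnames(mat) %in% design$sample))
  cond <- design$condition[match(colnames(mat), design$sample)]
  lev <- if (is.factor(design$condition)) levels(design$condition) else unique(cond)
  if (length(lev) < 2L) stop("need at least 2 sampling points")
  med <- vapply(lev, function(cv)
    apply(mat[, cond == cv, drop = FALSE], 1L, median), numeric(nrow(mat)))
  if (is.null(dim(med))) med <- matrix(med, nrow = 1L, dimnames = list(rownames(mat), lev))
  s <- apply(med, 1L, sd)
  flat <- s == 0 | is.na(s)
  if (any(flat)) {
    warning(sum(flat), " constant profile(s) dropped")
    med <- med[!flat, , drop = FALSE]
    s <- s[!flat]
  }
  (med - rowMeans(med)) / s
}

#' Fuzzy c-means soft clustering of expression profiles
#'
#' Standard fuzzy c-means with Euclidean distance: memberships
#' `u_ik = 1 / sum_j (d_ik / d_jk)^(2/(m-1))`, centers as the
#' membership^m-weighted means, iterated until the largest center shift is
#' below `tol` or `max_iter` is reached. Initial centers are `c` distinct
#' profiles drawn with the given seed, so a fixed seed gives bit-identical
#' results. Genes whose maximum membership is below `cutoff` stay
#' unassigned.
#'
#' @param profiles Genes x points matrix (e.g. from
#'   [standardize_profiles]).
#' @param c Number of clusters (>= 2, < number of genes).
#' @param m Fuzzifier (> 1, default 2).
#' @param seed Integer seed for center initialisation.
#' @param cutoff Membership cutoff for hard assignment (default 0.7).
#' @param max_iter,tol Convergence controls.
#' @return List of class `fuzzy_clustering`: `centers` (c x points),
#'   `membership` (genes x c, rows sum to 1), `assigned` (named integer,
#'   `NA` when below cutoff), `m`, `cutoff`, `iterations`.
#' @export
fuzzy_cmeans <- function(profiles, c, m = 2, seed = 1, cutoff = 0.7,
                         max_iter = 1000, tol = 1e-8) {
  x <- as.matrix(profiles)
  ng <- nrow(x)
  stopifnot(c >= 2, m > 1)
  if (c > ng) stop("more clusters than genes")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  init <- sample.int(ng, c)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  centers <- x[init, , drop = FALSE] +
    matrix(seq_len(c) * 1e-9, nrow = c, ncol = ncol(x))  # break exact ties
  u <- matrix(0, ng, c)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- outer(rowSums(x^2), rep(1, c)) - 2 * x %*% t(centers) +
      outer(rep(1, ng), rowSums(centers^2))
    d2 <- pmax(d2, 0)
    pw <- d2^(-1 / (m - 1))
    zero <- d2 < 1e-300
    u <- pw / rowSums(pw)
    if (any(zero)) {  # profile coincides with a center
      for (i in which(rowSums(zero) > 0L)) {
        u[i, ] <- zero[i, ] / sum(zero[i, ])
      }
    }
    um <- u^m
    newc <- t(um) %*% x / colSums(um)
    shift <- max(abs(newc - centers))
    centers <- newc
    if (shift < tol || iter >= max_iter) break
  }
  rownames(centers) <- paste0("cluster", seq_len(c))
  dimnames(u) <- list(rownames(x), rownames(centers))
  amax <- apply(u, 1L, which.max)
  assigned <- ifelse(u[cbind(seq_len(ng), amax)] >= cutoff, amax, NA_integer_)
  names(assigned) <- rownames(x)
  structure(list(centers = centers, membership = u, assigned = assigned,
                 m = m, cutoff = cutoff, iterations = iter),
            class = "fuzzy_clustering")
}

#' @export
print.fuzzy_clustering <- function(x, ...) {
  cat(sprintf("fuzzy_cmeans: %d clusters, %d genes (%d assigned at cutoff %.2f), %d iterations\n",
              nrow(x$centers), nrow(x$membership),
              sum(!is.na(x$assigned)), x$cutoff, x$iterations))
  invisible(x)
}

#' Minimum-centroid-distance curve for choosing the cluster number
#'
#' For each candidate `c`, fuzzy c-means is repeated `repeats` times with
#' distinct seeds and Dmin(c) is the mean, over runs, of the minimum
#' pairwise Euclidean distance between cluster centers. The elbow — where
#' adding clusters yields only a minimal decrease — indicates a sensible
#' `c`; the choice itself is left to inspection.
#'
#' @param profiles Genes x points matrix.
#' @param c_range Integer vector of candidate cluster numbers.
#' @param repeats Runs per candidate (default 10).
#' @param seeds Optional matrix/vector of seeds; defaults to
#'   `seed + 1:repeats` per candidate.
#' @param seed Base seed when `seeds` is not given.
#' @param m Fuzzifier.
#' @return data.frame `c`, `dmin` (mean), `dmin_sd` across runs.
#' @export
select_k_dmin <- function(profiles, c_range = 2:8, repeats = 10, seeds = NULL,
                          seed = 1, m = 2) {
  stopifnot(all(c_range >= 2), all(c_range < nrow(profiles)))
  if (is.null(seeds)) seeds <- seed + seq_len(repeats)
  rows <- lapply(c_range, function(cc) {
    dmins <- vapply(seeds, function(s) {
      fit <- fuzzy_cmeans(profiles, c = cc, m = m, seed = s, max_iter = 200)
      min(dist(fit$centers))
    }, numeric(1))
    data.frame(c = cc, dmin = mean(dmins), dmin_sd = sd(dmins))
  })
  do.call(rbind, rows)
}
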