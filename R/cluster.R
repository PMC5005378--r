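#' Cluster-based permutation test on paired difference maps
#'
#' The shared engine behind [compare_spectra()] (1-D frequency axis) and
#' [cluster_compare()] (2-D comodulograms).  Cell-wise paired t statistics
#' are thresholded at two-sided `thresh_p`; suprathreshold cells are grouped
#' into contiguous clusters (runs in 1-D, 4-connected components in 2-D) and
#' each cluster's integrated t (sign retained) is compared to the null
#' distribution of the maximum absolute cluster mass over sign-flip
#' permutations of the subject difference maps.  Cells that are `NA` for any
#' subject are excluded.
#'
#' @param diffs subjects x cells matrix of paired differences (cells in
#'   column-major order of the `dims` grid).
#' @param dims `c(nrow, ncol)` of the cell grid; `c(1, n)` for a 1-D axis.
#' @param n_perm number of sign-flip permutations (>= 100 advised).
#' @param thresh_p two-sided cell threshold (default 0.01).
#' @param cluster_p cluster significance level (default 0.05).
#' @param seed RNG seed.
#' @return a `cluster_test`: `t` (matrix of t values), `t_crit`, `clusters`
#'   (list of `cells`, `mass`, `p`, `significant`), `null_max_mass`.
#' @export
cluster_perm_test <- function(diffs, dims, n_perm = 500, thresh_p = 0.01,
                              cluster_p = 0.05, seed = 1) {
  diffs <- as.matrix(diffs)
  n <- nrow(diffs)
  if (n < 3) stop("need >= 3 paired subjects")
  if (n_perm < 100) warning("n_perm < 100: cluster p-values will be coarse")
  ok <- !apply(is.na(diffs), 2, any)
  ss <- colSums(diffs^2)
  t_of <- function(m) {                        # t from means, fixed sum sq
    v <- (ss - n * m^2) / (n - 1)
    ifelse(ok & v > 0, m / sqrt(v / n), NA_real_)
  }
  t_obs <- t_of(colMeans(diffs))
  t_crit <- stats::qt(1 - thresh_p / 2, df = n - 1)

  cl <- find_clusters(t_obs, dims, t_crit)
  null_max <- numeric(n_perm)
  with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    for (b in seq_len(n_perm)) {
      tb <- t_of(as.numeric(signs[b, ] %*% diffs) / n)
      cb <- find_clusters(tb, dims, t_crit)
      null_max[b] <- if (length(cb)) max(abs(vapply(cb, `[[`, 0, "mass"))) else 0
    }
  })
  clusters <- lapply(cl, function(cc) {
    p <- (1 + sum(null_max >= abs(cc$mass))) / (n_perm + 1)
    c(cc, list(p = p, significant = p < cluster_p))
  })
  structure(list(t = matrix(t_obs, dims[1], dims[2]), t_crit = t_crit,
                 clusters = clusters, null_max_mass = null_max,
                 n_perm = n_perm, thresh_p = thresh_p, cluster_p = cluster_p),
            class = "cluster_test")
}

# contiguous suprathreshold clusters; positive and negative cells clustered
# separately; 4-connectivity on the dims grid (column-major cell indices)
find_clusters <- function(tv, dims, t_crit) {
  out <- list()
  for (sgn in c(1, -1)) {
    mask <- !is.na(tv) & sgn * tv > t_crit
    lab <- label_components(mask, dims)
    for (g in seq_len(max(lab, 0))) {
      cells <- which(lab == g)
      out[[length(out) + 1]] <- list(cells = cells, mass = sum(tv[cells]))
    }
  }
  out
}

label_components <- function(mask, dims) {
  nr <- dims[1]; nc <- dims[2]
  lab <- integer(length(mask))
  cur <- 0L
  for (s in which(mask)) {
    if (lab[s]) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      i <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[i]) next
      lab[i] <- cur
      r <- (i - 1L) %% nr + 1L; cc <- (i - 1L) %/% nr + 1L
      nb <- c(if (r > 1) i - 1L, if (r < nr) i + 1L,
              if (cc > 1) i - nr, if (cc < nc) i + nr)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      stack <- c(stack, nb)
    }
  }
  lab
}

#' @export
print.cluster_test <- function(x, ...) {
  ns <- sum(vapply(x$clusters, `[[`, TRUE, "significant"))
  cat(sprintf("Cluster permutation test: %d cluster(s), %d significant at p < %g (%d permutations)\n",
              length(x$clusters), ns, x$cluster_p, x$n_perm))
  for (cc in x$clusters)
    cat(sprintf("  cells %d..%d  mass %.2f  p = %.4f%s\n", min(cc$cells),
                max(cc$cells), cc$mass, cc$p, if (cc$significant) " *" else ""))
  invisible(x)
}
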