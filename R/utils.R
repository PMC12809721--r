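#' Discrete-cosine high-pass basis
#'
#' DCT regressors spanning fluctuations slower than `cutoff` seconds, the
#' standard drift model for fMRI time series: basis k has frequency
#' k / (2 L) and all k with frequency below 1/cutoff are included.
#'
#' @param n number of time points.
#' @param tr sampling interval, seconds.
#' @param cutoff high-pass cutoff period, seconds.
#' @return matrix with `n` rows (possibly zero columns).
#' @export
dct_basis <- function(n, tr = 1, cutoff = 90) {
  len <- n * tr
  K <- floor(2 * len / cutoff)
  if (K < 1) return(matrix(numeric(0), nrow = n, ncol = 0))
  t_idx <- seq_len(n) - 0.5
  out <- vapply(seq_len(K), function(k) cos(pi * k * t_idx / n),
                numeric(n))
  colnames(out) <- paste0("dct", seq_len(K))
  out
}

#' Convert t statistics to Z scores
#'
#' Tail-probability equivalent normal deviates, computed on the log scale
#' so large statistics do not saturate.
#'
#' @param t numeric vector of t statistics.
#' @param df degrees of freedom.
#' @return numeric vector of Z scores.
#' @export
zstat_from_t <- function(t, df) {
  lp <- stats::pt(abs(t), df, lower.tail = FALSE, log.p = TRUE)
  z <- -stats::qnorm(lp, log.p = TRUE)
  z * sign(t)
}

#' Connected components of a 3D logical array
#'
#' Face connectivity (6 neighbours), union-find over adjacent voxel
#' pairs. Used for cluster-extent inference on statistic maps.
#'
#' @param mask 3D logical array.
#' @return integer array of the same shape: 0 outside, cluster labels
#'   (1..K, in decreasing size order) inside.
#' @export
label_clusters <- function(mask) {
  dims <- dim(mask)
  stopifnot(length(dims) == 3)
  lab <- array(0L, dims)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  rank_of <- integer(prod(dims))
  rank_of[idx] <- seq_along(idx)

  parent <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }

  strides <- c(1L, dims[1], dims[1] * dims[2])
  coord <- arrayInd(idx, dims)
  for (ax in 1:3) {
    ok <- coord[, ax] < dims[ax]
    nb <- idx[ok] + strides[ax]
    both <- mask[nb]
    a <- rank_of[idx[ok][both]]
    b <- rank_of[nb[both]]
    for (k in seq_along(a)) {
      ra <- find(a[k]); rb <- find(b[k])
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  sizes <- table(roots)
  ord <- order(sizes, decreasing = TRUE)
  relabel <- integer(max(as.integer(names(sizes))))
  relabel[as.integer(names(sizes))[ord]] <- seq_along(sizes)
  lab[idx] <- relabel[roots]
  lab
}

#' Sizes of labelled clusters
#' @param lab output of [label_clusters()].
#' @return integer vector of cluster sizes (possibly empty).
#' @export
cluster_sizes <- function(lab) {
  s <- tabulate(lab[lab > 0])
  s[s > 0]
}

# residualize columns of Y (obs x var) on centred covariates, keeping the
# mean; X is a data.frame or matrix of covariates (may be NULL)
residualize_matrix <- function(Y, covariates = NULL) {
  if (is.null(covariates) || NCOL(covariates) == 0) {
    return(list(Y = Y, q = 0L))
  }
  X <- stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1,
                                                                  drop = FALSE]
  X <- scale(X, center = TRUE, scale = FALSE)
  qrX <- qr(X)
  list(Y = Y - qr.fitted(qrX, Y), q = qrX$rank)
}
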