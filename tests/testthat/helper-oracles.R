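# Independent reference implementations used to validate the package's
# algorithms. These deliberately share no code with R/: distances use the
# spherical law of cosines, centroids are recomputed from scratch, and the
# REML criterion is maximized directly on dense matrices.

oracle_dist_m <- function(lat1, lon1, lat2, lon2) {
  f1 <- lat1 * pi / 180; f2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  x <- sin(f1) * sin(f2) + cos(f1) * cos(f2) * cos(dl)
  6371000 * acos(pmin(1, pmax(-1, x)))
}

# maximal within-threshold runs -> dwell filter -> same-locality merge ->
# sequential centroid agglomeration; mirrors the documented contract, written
# naively (O(n^2) centroid recomputation)
oracle_detect_stays <- function(fixes, config) {
  t <- as.numeric(fixes$time); lat <- fixes$lat; lon <- fixes$lon
  n <- length(t)
  runs <- list(); cur <- 1L
  if (n >= 2) {
    for (i in 2:n) {
      g <- cur[1]:cur[length(cur)]
      ok <- (t[i] - t[i - 1]) <= config$merge_gap_s &&
        oracle_dist_m(lat[i], lon[i], mean(lat[cur]), mean(lon[cur])) <=
          config$spatial_m
      if (ok) cur <- c(cur, i) else { runs[[length(runs) + 1L]] <- cur; cur <- i }
    }
  }
  runs[[length(runs) + 1L]] <- cur
  keep <- Filter(function(ix) t[ix[length(ix)]] - t[ix[1]] >= config$min_dwell_s,
                 runs)
  if (!length(keep)) {
    return(list(visits = data.frame(start = numeric(), end = numeric()),
                fix_cluster = rep(NA_integer_, n)))
  }
  # merge consecutive visits at the same locality across short gaps
  merged <- list(keep[[1]])
  if (length(keep) > 1) {
    for (k in 2:length(keep)) {
      prev <- merged[[length(merged)]]
      curv <- keep[[k]]
      gap <- t[curv[1]] - t[prev[length(prev)]]
      d <- oracle_dist_m(mean(lat[curv]), mean(lon[curv]),
                         mean(lat[prev]), mean(lon[prev]))
      if (gap <= config$merge_gap_s && d <= config$spatial_m) {
        merged[[length(merged)]] <- c(prev, curv)
      } else merged[[length(merged) + 1L]] <- curv
    }
  }
  # agglomerate into clusters (dwell-weighted running centroids)
  cl_of <- integer(length(merged))
  cls <- list()
  for (k in seq_along(merged)) {
    v <- merged[[k]]
    vc <- c(mean(lat[v]), mean(lon[v]))
    dw <- t[v[length(v)]] - t[v[1]]
    assigned <- FALSE
    if (length(cls)) {
      d <- vapply(cls, function(cl)
        oracle_dist_m(vc[1], vc[2], cl$lat, cl$lon), 0)
      j <- which.min(d)
      if (d[j] <= config$spatial_m) {
        cl <- cls[[j]]
        cls[[j]] <- list(lat = (cl$lat * cl$w + vc[1] * dw) / (cl$w + dw),
                         lon = (cl$lon * cl$w + vc[2] * dw) / (cl$w + dw),
                         w = cl$w + dw)
        cl_of[k] <- j; assigned <- TRUE
      }
    }
    if (!assigned) {
      cls[[length(cls) + 1L]] <- list(lat = vc[1], lon = vc[2], w = dw)
      cl_of[k] <- length(cls)
    }
  }
  fix_cluster <- rep(NA_integer_, n)
  for (k in seq_along(merged)) fix_cluster[merged[[k]]] <- cl_of[k]
  list(visits = data.frame(
         start = vapply(merged, function(v) t[v[1]], 0),
         end = vapply(merged, function(v) t[v[length(v)]], 0),
         cluster = cl_of),
       fix_cluster = fix_cluster)
}

# direct dense profiled-REML maximization for Gaussian mixed models with
# random intercepts; groups = list of grouping vectors
oracle_reml <- function(y, X, groups) {
  n <- length(y)
  Zs <- lapply(groups, function(g) stats::model.matrix(~ 0 + factor(g)))
  crit <- function(logv) {
    V <- diag(exp(logv[length(logv)]), n)
    for (j in seq_along(Zs)) V <- V + exp(logv[j]) * tcrossprod(Zs[[j]])
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    ldV <- 2 * sum(log(diag(ch)))
    Vi <- chol2inv(ch)
    XtViX <- crossprod(X, Vi %*% X)
    beta <- solve(XtViX, crossprod(X, Vi %*% y))
    r <- y - X %*% beta
    as.numeric(0.5 * (ldV + determinant(XtViX, logarithm = TRUE)$modulus +
                        crossprod(r, Vi %*% r)))
  }
  v0 <- rep(log(stats::var(y) / (length(Zs) + 1)), length(Zs) + 1)
  op <- stats::optim(v0, crit, method = "Nelder-Mead",
                     control = list(reltol = 1e-14, maxit = 10000))
  op <- stats::optim(op$par, crit, method = "Nelder-Mead",
                     control = list(reltol = 1e-14, maxit = 10000))
  vhat <- exp(op$par)
  V <- diag(vhat[length(vhat)], n)
  for (j in seq_along(Zs)) V <- V + vhat[j] * tcrossprod(Zs[[j]])
  Vi <- chol2inv(chol(V))
  beta <- solve(crossprod(X, Vi %*% X), crossprod(X, Vi %*% y))
  list(beta = as.numeric(beta), variances = vhat)
}

oracle_binomial_tail <- function(n, k, p0) {
  if (k == 0) return(1)
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}
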