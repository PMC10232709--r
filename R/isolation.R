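#' Great-circle and latitudinal distances
#'
#' `crow_flies` is the haversine great-circle distance (mean Earth radius
#' 6371.0088 km); `latitude_distance` is the absolute latitude difference
#' converted at 111.195 km per degree (mean-radius meridian).
#'
#' @param a,b coordinate pairs `c(lon, lat)` in degrees.
#' @return distance in km.
#' @export
crow_flies <- function(a, b) {
  .check_coord(a); .check_coord(b)
  geosphere::distHaversine(a, b, r = 6371.0088)
}

#' @rdname crow_flies
#' @export
latitude_distance <- function(a, b) {
  .check_coord(a); .check_coord(b)
  abs(a[2] - b[2]) * 111.195
}

.check_coord <- function(x) {
  if (length(x) != 2 || !is.finite(x[1]) || !is.finite(x[2]) ||
      abs(x[1]) > 180 || abs(x[2]) > 90)
    stop("invalid lon/lat coordinate")
  invisible(x)
}

#' Raster coastline distance
#'
#' Distance along a coastline polyline between two points, modelled as the
#' total length of the diagonals of all `grid`-km cells the sub-path passes
#' through: the polyline section between the vertices nearest to `a` and
#' `b` is traversed, every cell crossed with positive length is counted
#' once, and the distance is `n_cells * grid * sqrt(2)`.
#'
#' @param coast data.frame of ordered projected vertices (columns x, y, km).
#' @param a,b projected points `c(x, y)` in km, snapped to the nearest
#'   polyline vertex.
#' @param grid cell size in km (default 0.1).
#' @param snap_radius maximum allowed snap distance in km (default 50).
#' @return distance in km.
#' @export
coastline_distance <- function(coast, a, b, grid = 0.1, snap_radius = 50) {
  snap <- function(pt) {
    d2 <- (coast$x - pt[1])^2 + (coast$y - pt[2])^2
    i <- which.min(d2)
    if (sqrt(d2[i]) > snap_radius)
      stop("point farther than snap radius (", snap_radius, " km) from coastline")
    i
  }
  ia <- snap(a); ib <- snap(b)
  if (ia == ib) return(0)
  idx <- seq(min(ia, ib), max(ia, ib))
  xs <- coast$x[idx]; ys <- coast$y[idx]
  cells <- new.env(hash = TRUE)
  for (k in seq_len(length(idx) - 1)) {
    x0 <- xs[k] / grid; y0 <- ys[k] / grid
    x1 <- xs[k + 1] / grid; y1 <- ys[k + 1] / grid
    dx <- x1 - x0; dy <- y1 - y0
    tcross <- c(0, 1)
    if (dx != 0) {
      gx <- seq(ceiling(min(x0, x1)), floor(max(x0, x1)))
      tcross <- c(tcross, (gx - x0) / dx)
    }
    if (dy != 0) {
      gy <- seq(ceiling(min(y0, y1)), floor(max(y0, y1)))
      tcross <- c(tcross, (gy - y0) / dy)
    }
    tcross <- sort(unique(pmin(pmax(tcross, 0), 1)))
    if (length(tcross) < 2) next
    tm <- (utils::head(tcross, -1) + utils::tail(tcross, -1)) / 2
    seglen <- diff(tcross)
    cx <- floor(x0 + tm * dx); cy <- floor(y0 + tm * dy)
    ok <- seglen > 1e-12
    for (key in unique(paste(cx[ok], cy[ok]))) assign(key, TRUE, envir = cells)
  }
  length(ls(cells)) * grid * sqrt(2)
}

#' Robust annual SST summaries
#'
#' Removes the five values with the largest absolute deviation from the
#' median of the series (guarding against recording spikes), then returns
#' the maximum, minimum and mean of the remainder. Order-invariant.
#'
#' @param series numeric SST series (monthly, length >= 17 so that at least
#'   a full year remains).
#' @param n_outliers number of extreme deviations to drop (default 5).
#' @return named vector sst_max, sst_min, sst_mean (deg C).
#' @export
sst_summaries <- function(series, n_outliers = 5) {
  if (length(series) < n_outliers + 12)
    stop("SST series too short: need at least ", n_outliers + 12, " values")
  dev <- abs(series - stats::median(series))
  keep <- order(dev, decreasing = TRUE)[-seq_len(n_outliers)]
  x <- series[keep]
  c(sst_max = max(x), sst_min = min(x), sst_mean = mean(x))
}

#' Build the pairwise isolation table
#'
#' One row per unordered site pair: linearised genetic distance
#' Fst / (1 - Fst), the three geographic distances (coastline raster,
#' great-circle, latitudinal; km) and the absolute differences of the
#' robust SST summaries (deg C).
#'
#' @param sites data.frame with site, lon, lat and (for the coastline
#'   distance) the projected anchor coordinates via `coast` + `anchor`
#'   column, as produced by [simulate_geography()].
#' @param coast projected coastline polyline (x, y in km).
#' @param sst site-by-month SST matrix (rownames = site).
#' @param fst symmetric pairwise site Fst matrix, or a data.frame
#'   site1/site2/gdist of ready-made linearised distances.
#' @param grid raster cell size for the coastline distance (km).
#' @return data.frame: site1, site2, gdist, d_csl, d_crf, d_lat, dsst_max,
#'   dsst_min, dsst_mean.
#' @export
build_isolation_table <- function(sites, coast, sst, fst, grid = 0.1) {
  stopifnot(nrow(sites) >= 3)
  summ <- t(apply(sst[sites$site, , drop = FALSE], 1, sst_summaries))
  pr <- t(utils::combn(nrow(sites), 2))
  lin <- function(f) f / (1 - f)
  rows <- lapply(seq_len(nrow(pr)), function(k) {
    i <- pr[k, 1]; j <- pr[k, 2]
    si <- sites$site[i]; sj <- sites$site[j]
    g <- if (is.matrix(fst)) lin(fst[si, sj]) else {
      hit <- (fst$site1 == si & fst$site2 == sj) |
        (fst$site1 == sj & fst$site2 == si)
      fst$gdist[hit][1]
    }
    ai <- c(coast$x[sites$anchor[i]], coast$y[sites$anchor[i]])
    aj <- c(coast$x[sites$anchor[j]], coast$y[sites$anchor[j]])
    data.frame(
      site1 = si, site2 = sj, gdist = g,
      d_csl = coastline_distance(coast, ai, aj, grid = grid),
      d_crf = crow_flies(c(sites$lon[i], sites$lat[i]),
                         c(sites$lon[j], sites$lat[j])),
      d_lat = latitude_distance(c(sites$lon[i], sites$lat[i]),
                                c(sites$lon[j], sites$lat[j])),
      dsst_max = abs(summ[si, "sst_max"] - summ[sj, "sst_max"]),
      dsst_min = abs(summ[si, "sst_min"] - summ[sj, "sst_min"]),
      dsst_mean = abs(summ[si, "sst_mean"] - summ[sj, "sst_mean"]))
  })
  do.call(rbind, rows)
}

#' Simple OLS fit of a distance on one predictor
#'
#' @param y response vector.
#' @param x predictor vector.
#' @return list with slope, intercept, p (slope t-test), r_squared.
#' @export
fit_ols <- function(y, x) {
  if (length(y) <= 2) stop("need more than 2 observations")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       p = s$coefficients[2, 4], r_squared = s$r.squared)
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j), with R^2_j from regressing predictor j on the
#' remaining predictors.
#'
#' @param X numeric matrix or data.frame of predictors (>= 2 columns).
#' @return named numeric vector of VIFs.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  stopifnot(ncol(X) >= 2, nrow(X) > ncol(X) + 1)
  vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm(X[, j] ~ X[, -j, drop = FALSE])
    r2 <- summary(fit)$r.squared
    if (r2 > 1 - 1e-12)
      stop("singular design: predictor ", colnames(X)[j],
           " is collinear with the others")
    1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) |> stats::setNames(colnames(X))
}

#' Regularized (elastic-net) regression
#'
#' Fits y on standardized predictors with the elastic-net penalty.
#' `l1_ratio = 1` is the LASSO, `0` is ridge. `lambda = 0` is the exact
#' unpenalised limit and is solved by least squares directly. When `lambda`
#' is `NULL` it is chosen by seeded 5-fold cross-validation. Coefficients
#' are reported on the standardized scale.
#'
#' @param y response.
#' @param X predictor matrix / data.frame.
#' @param l1_ratio elastic-net mixing parameter in \[0, 1\].
#' @param lambda penalty, or NULL for cross-validation.
#' @param seed seed for the cross-validation folds.
#' @return list with coefficients (standardized scale), lambda, r_squared.
#' @export
fit_regularized <- function(y, X, l1_ratio = 0.5, lambda = NULL, seed = 1) {
  X <- as.matrix(X)
  Xs <- scale(X)
  yc <- y - mean(y)
  if (!is.null(lambda) && length(lambda) == 1 && lambda == 0) {
    beta <- stats::coef(stats::lm(yc ~ Xs - 1))
    fitted <- Xs %*% beta
  } else {
    if (is.null(lambda)) {
      set.seed(seed)
      foldid <- sample(rep_len(1:5, length(y)))
      cv <- glmnet::cv.glmnet(Xs, yc, alpha = l1_ratio, foldid = foldid,
                              standardize = FALSE, intercept = FALSE)
      lambda <- cv$lambda.min
    }
    fit <- glmnet::glmnet(Xs, yc, alpha = l1_ratio, lambda = lambda,
                          standardize = FALSE, intercept = FALSE,
                          thresh = 1e-12)
    beta <- as.numeric(fit$beta)
    fitted <- Xs %*% beta
  }
  names(beta) <- colnames(X)
  r2 <- 1 - sum((yc - fitted)^2) / sum(yc^2)
  list(coefficients = beta, lambda = lambda, r_squared = r2)
}

# k-subsets of an index vector (scalar-safe, unlike combn on a scalar)
.ksubsets <- function(x, k) {
  if (k == 0) return(list(integer(0)))
  if (length(x) == 1) return(if (k == 1) list(x) else list())
  utils::combn(x, k, simplify = FALSE)
}

# R^2 of y on the subset of columns `S` of standardized X (empty set -> 0)
.subset_r2 <- function(ys, Xs, S) {
  if (!length(S)) return(0)
  fit <- stats::lm.fit(cbind(1, Xs[, S, drop = FALSE]), ys)
  1 - sum(fit$residuals^2) / sum((ys - mean(ys))^2)
}

#' Weighted multiple-regression decomposition
#'
#' Dissects the R^2 of the multiple regression of a genetic distance on a
#' set of collinear predictors into per-predictor indices: validity
#' coefficient (zero-order correlation with y), structure coefficient
#' (correlation with the fitted values, = validity / sqrt(R^2)), unique
#' coefficient (R^2 drop when the predictor is removed), commonality
#' coefficient (validity^2 - unique: variance shared with other
#' predictors), general dominance (average incremental R^2 over all subset
#' sizes, whose sum is R^2) and Johnson's relative weight (orthogonal
#' approximation via SVD, sum also R^2). All-subset R^2 values are computed
#' exhaustively, so p is capped at 12.
#'
#' @param y response (e.g. linearised genetic distance per site pair).
#' @param X predictor matrix / data.frame (standardized internally).
#' @return data.frame (one row per predictor plus a `.total` row) with the
#'   indices above; model R^2 as attribute `r_squared`.
#' @export
mlr_decomposition <- function(y, X) {
  X <- as.matrix(X)
  p <- ncol(X); n <- nrow(X)
  if (p > 12) stop("p > 12: refusing 2^p all-subsets scan; drop predictors")
  if (n <= p + 1) stop("need n > p + 1")
  Xs <- scale(X); ys <- as.numeric(scale(y))
  validity <- as.numeric(stats::cor(Xs, ys))
  subsets <- lapply(seq_len(2^p - 1), function(m) which(bitwAnd(m, 2^(0:(p - 1))) > 0))
  r2 <- vapply(subsets, function(S) .subset_r2(ys, Xs, S), numeric(1))
  r2_of <- function(S) if (!length(S)) 0 else r2[[sum(2^(S - 1))]]
  R2 <- r2_of(seq_len(p))
  unique_c <- vapply(seq_len(p), function(j)
    R2 - r2_of(setdiff(seq_len(p), j)), numeric(1))
  commonality <- validity^2 - unique_c
  structure_c <- validity / sqrt(R2)
  gd <- vapply(seq_len(p), function(j) {
    others <- setdiff(seq_len(p), j)
    inc_by_size <- vapply(0:(p - 1), function(k) {
      ss <- .ksubsets(others, k)
      mean(vapply(ss, function(S) r2_of(c(S, j)) - r2_of(S), numeric(1)))
    }, numeric(1))
    mean(inc_by_size)
  }, numeric(1))
  # Johnson's relative weights by orthogonal approximation
  sv <- svd(Xs)
  Z <- sv$u %*% t(sv$v)                      # orthonormal columns
  b <- as.numeric(crossprod(Z, ys))
  Lam <- sv$v %*% diag(sv$d, p) %*% t(sv$v)  # X = Z %*% Lam
  lam2 <- Lam^2 / (n - 1)                    # rows sum to 1
  rw <- as.numeric(lam2 %*% (b^2)) / (n - 1)
  out <- data.frame(
    predictor = colnames(X),
    validity = validity,
    structure = structure_c,
    structure_sq = structure_c^2,
    unique = unique_c,
    commonality = commonality,
    general_dominance = gd,
    relative_weight = rw)
  total <- data.frame(predictor = ".total", validity = NA, structure = NA,
                      structure_sq = sum(structure_c^2),
                      unique = sum(unique_c),
                      commonality = sum(commonality),
                      general_dominance = sum(gd),
                      relative_weight = sum(rw))
  res <- rbind(out, total)
  attr(res, "r_squared") <- R2
  res
}

#' Bootstrap confidence intervals for the decomposition indices
#'
#' Case resampling of the site-pair rows; percentile 2.5/97.5 intervals for
#' every index of [mlr_decomposition()]. Degenerate resamples (constant
#' column or singular decomposition) are redrawn and counted.
#'
#' @param y,X as in [mlr_decomposition()].
#' @param B bootstrap replicates (default 5000).
#' @param seed RNG seed.
#' @return list with `ci` (data.frame: predictor, index, lower, upper),
#'   `n_redrawn`.
#' @export
bootstrap_ci <- function(y, X, B = 5000, seed = 1) {
  X <- as.matrix(X)
  set.seed(seed)
  idx_cols <- c("validity", "structure", "unique", "commonality",
                "general_dominance", "relative_weight")
  n <- nrow(X)
  reps <- vector("list", B)
  n_redrawn <- 0
  for (b in seq_len(B)) {
    repeat {
      i <- sample.int(n, n, replace = TRUE)
      res <- tryCatch({
        if (any(apply(X[i, , drop = FALSE], 2, stats::sd) == 0) ||
            stats::sd(y[i]) == 0) stop("degenerate")
        mlr_decomposition(y[i], X[i, , drop = FALSE])
      }, error = function(e) NULL)
      if (!is.null(res)) break
      n_redrawn <- n_redrawn + 1
    }
    reps[[b]] <- res
  }
  preds <- reps[[1]]$predictor
  ci <- do.call(rbind, lapply(idx_cols, function(v) {
    do.call(rbind, lapply(seq_along(preds), function(r) {
      vals <- vapply(reps, function(d) d[[v]][r], numeric(1))
      if (all(is.na(vals))) return(NULL)
      qs <- stats::quantile(vals, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
      data.frame(predictor = preds[r], index = v,
                 lower = qs[1], upper = qs[2])
    }))
  }))
  rownames(ci) <- NULL
  list(ci = ci, n_redrawn = n_redrawn)
}
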