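#' Flag in-transition fixes and cluster stationary GPS fixes
#'
#' Each fix gets a speed (haversine distance to the previous fix divided
#' by elapsed time); fixes moving faster than 1 km/h are flagged
#' in-transition. Stationary fixes are clustered by density (DBSCAN-style,
#' 30 m radius, minimum 5 fixes) after snapping to a 5 m grid — grid cells
#' carry their fix multiplicity, so results match point-level DBSCAN to
#' within the snap resolution. Noise fixes stay unclustered (`NA`).
#'
#' @param fixes Data frame with `t` (seconds), `lat`, `lon`, sorted by `t`.
#' @param eps_m Neighborhood radius in meters.
#' @param min_pts Minimum weighted neighborhood size for a core cell.
#' @return List: `transition` (logical per fix), `cluster` (integer per
#'   fix, `NA` for in-transition or noise fixes), `n_clusters`, `speed_kmh`.
#'   `NULL` when fewer than 2 fixes are available.
#' @export
cluster_locations <- function(fixes, eps_m = 30, min_pts = 5) {
  n <- nrow(fixes)
  if (n < 2) return(NULL)
  d <- haversine_m(fixes$lat[-n], fixes$lon[-n], fixes$lat[-1], fixes$lon[-1])
  dt <- diff(fixes$t)
  speed_kmh <- c(0, ifelse(dt > 0, d / dt * 3.6, 0))
  transition <- speed_kmh > 1
  cluster <- rep(NA_integer_, n)
  st <- which(!transition)
  n_clusters <- 0L
  if (length(st) >= min_pts) {
    xy <- equirect_xy(fixes$lat[st], fixes$lon[st])
    gx <- round(xy$x / 5)
    gy <- round(xy$y / 5)
    key <- paste(gx, gy)
    cells <- !duplicated(key)
    ux <- xy$x[cells]; uy <- xy$y[cells]; ukey <- key[cells]
    w <- as.vector(table(key)[ukey])
    u <- length(ux)
    # weighted DBSCAN on unique grid cells
    D2 <- outer(ux, ux, "-")^2 + outer(uy, uy, "-")^2
    nb <- D2 <= eps_m^2
    wsum <- as.vector(nb %*% w)
    core <- wsum >= min_pts
    lab <- rep(NA_integer_, u)
    cid <- 0L
    for (i in which(core)) {
      if (!is.na(lab[i])) next
      cid <- cid + 1L
      frontier <- i
      lab[i] <- cid
      while (length(frontier)) {
        nbrs <- which(nb[frontier[1], ] & core & is.na(lab))
        lab[nbrs] <- cid
        frontier <- c(frontier[-1], nbrs)
      }
    }
    # border cells join the cluster of any core cell within eps
    for (i in which(!core)) {
      cand <- which(nb[i, ] & core)
      if (length(cand)) lab[i] <- lab[cand[1]]
    }
    n_clusters <- cid
    cluster[st] <- lab[match(key, ukey)]
  }
  list(transition = transition, cluster = cluster,
       n_clusters = n_clusters, speed_kmh = speed_kmh)
}

#' Location feature family over one 14-day window
#'
#' Computes the seven GPS mobility features: `loc_variance`
#' (log of var(lat)+var(lon) over stationary fixes), `loc_unique_locations`
#' (density-cluster count), `loc_entropy` and `loc_entropy_norm` (Shannon
#' entropy of the stationary-fix distribution over clusters, nats, and its
#' ratio to log cluster count), `loc_home_frac` (fraction of stationary
#' fixes in the home cluster — the plurality cluster between 00:00 and
#' 06:00, falling back to the overall plurality cluster when there are no
#' nighttime fixes), `loc_pct_transition`, and `loc_circadian_movement`
#' (log of the summed least-squares spectral power fraction of latitude
#' and longitude in the 23.5–24.5 h band, each normalized by total power
#' over 2–26 h periods).
#'
#' @param fixes Data frame of fixes in the window (`t`, `lat`, `lon`).
#' @param clusters Output of [cluster_locations()] on those fixes.
#' @return Named numeric vector of the 7 features (NA when undefined).
#' @export
compute_location_features <- function(fixes, clusters) {
  feat <- c(loc_variance = NA_real_, loc_unique_locations = NA_real_,
            loc_entropy = NA_real_, loc_entropy_norm = NA_real_,
            loc_home_frac = NA_real_, loc_pct_transition = NA_real_,
            loc_circadian_movement = NA_real_)
  if (is.null(clusters)) return(feat)
  st <- !clusters$transition
  feat["loc_pct_transition"] <- mean(clusters$transition)
  if (sum(st) >= 2) {
    v <- var(fixes$lat[st]) + var(fixes$lon[st])
    feat["loc_variance"] <- log(max(v, 1e-12))
  }
  k <- clusters$n_clusters
  feat["loc_unique_locations"] <- k
  cl <- clusters$cluster
  clustered <- !is.na(cl)
  if (k >= 1 && any(clustered)) {
    p <- tabulate(cl[clustered], nbins = k)
    p <- p / sum(p)
    p <- p[p > 0]
    ent <- -sum(p * log(p))
    feat["loc_entropy"] <- ent
    if (k >= 2) feat["loc_entropy_norm"] <- ent / log(k)
    night <- clustered & (fixes$t %% SECONDS_PER_DAY) < 6 * 3600
    home <- if (any(night)) {
      as.integer(names(which.max(table(cl[night]))))
    } else {
      as.integer(names(which.max(table(cl[clustered]))))
    }
    feat["loc_home_frac"] <- sum(cl == home, na.rm = TRUE) / sum(st)
  }
  th <- fixes$t / 3600
  fr_lat <- ls_band_fraction(th, fixes$lat)
  fr_lon <- ls_band_fraction(th, fixes$lon)
  if (!is.na(fr_lat) || !is.na(fr_lon)) {
    s <- sum(c(fr_lat, fr_lon), na.rm = TRUE)
    feat["loc_circadian_movement"] <- log(max(s, 1e-12))
  }
  feat
}
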