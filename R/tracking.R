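#' Link localizations into trajectories
#'
#' Frame-to-frame minimum-cost one-to-one assignment on squared
#' displacement, with a hard per-link cap `max_disp_px`. Open track ends
#' compete for detections across gaps of up to `max_gap` missing frames.
#' Unassigned detections start new tracks. By default the assignment is
#' solved exactly per frame (Jonker-Volgenant); `method = "anneal"` uses a
#' simulated-annealing solver with geometric cooling, kept as an
#' alternative and tested to match the exact optimum on small instances.
#'
#' @param table a `LocalizationTable` sorted by frame.
#' @param max_disp_px maximum displacement per elapsed frame (pixels).
#' @param max_gap maximum number of consecutive missing frames bridged.
#' @param method `"exact"` or `"anneal"`.
#' @param seed integer seed making the annealing solver deterministic.
#' @return list of `Track` objects: `list(track_id, records, species)` where
#'   `records` is a data.frame of the member localizations.
#' @export
link_tracks <- function(table, max_disp_px = 5, max_gap = 2,
                        method = c("exact", "anneal"), seed = 1) {
  method <- match.arg(method)
  df <- as.data.frame(table)
  if (nrow(df) == 0) return(list())
  df <- df[order(df$frame), , drop = FALSE]
  df$.row <- seq_len(nrow(df))
  frames <- sort(unique(df$frame))
  assign_id <- rep(NA_integer_, nrow(df))
  # active tracks: list of (id, x, y, last_frame)
  act_id <- integer(0); act_x <- numeric(0); act_y <- numeric(0)
  act_f <- numeric(0)
  next_id <- 1L
  if (method == "anneal") set.seed(seed)
  for (f in frames) {
    rows <- which(df$frame == f)
    # drop expired tracks
    alive <- which(f - act_f <= max_gap + 1)
    nA <- length(alive); nD <- length(rows)
    j <- rep(NA_integer_, nA)
    if (nA > 0 && nD > 0) {
      gap <- f - act_f[alive]
      cost <- outer(act_x[alive], df$x[rows], "-")^2 +
              outer(act_y[alive], df$y[rows], "-")^2
      cap <- (max_disp_px * gap)^2
      cost[cost > cap] <- Inf   # per-row cap scales with the bridged gap
      maxc <- max(cap) + 1
      cost[!is.finite(cost)] <- Inf
      j <- if (method == "exact") {
        match_one_to_one(cost, max_cost = maxc)
      } else {
        anneal_match(cost, max_cost = maxc)
      }
      # reject links that exceed their own row's cap (anneal safety)
      bad <- which(!is.na(j) & cost[cbind(seq_len(nA), j)] > cap)
      if (length(bad)) j[bad] <- NA_integer_
    }
    matched_rows <- logical(nD)
    if (nA > 0) for (k in seq_len(nA)) {
      if (is.na(j[k])) next
      rr <- rows[j[k]]
      assign_id[rr] <- act_id[alive[k]]
      ai <- alive[k]
      act_x[ai] <- df$x[rr]; act_y[ai] <- df$y[rr]; act_f[ai] <- f
      matched_rows[j[k]] <- TRUE
    }
    for (k in which(!matched_rows)) {
      rr <- rows[k]
      assign_id[rr] <- next_id
      act_id <- c(act_id, next_id); act_x <- c(act_x, df$x[rr])
      act_y <- c(act_y, df$y[rr]); act_f <- c(act_f, f)
      next_id <- next_id + 1L
    }
  }
  df$track_id <- assign_id
  lapply(sort(unique(assign_id)), function(id) {
    rec <- df[df$track_id == id, setdiff(names(df), ".row"), drop = FALSE]
    rec <- rec[order(rec$frame), ]
    rownames(rec) <- NULL
    sp <- rec$species[!is.na(rec$species) & rec$species != "unassigned"]
    species <- if (length(sp)) names(sort(table(sp), decreasing = TRUE))[1]
               else NA_character_
    structure(list(track_id = id, records = rec, species = species),
              class = "Track")
  })
}

# Simulated-annealing assignment: minimizes the same capped cost as the
# exact solver. Geometric cooling from T0 = mean finite cost, factor 0.95,
# 1e4 proposals per restart, then a deterministic exchange polish; the best
# of `restarts` runs is kept. Rows may move to "unmatched" (cost max_cost).
anneal_match <- function(cost, max_cost, n_props = 1e4, t_factor = 0.95,
                         restarts = 3) {
  n <- nrow(cost)
  best <- NULL
  best_cost <- Inf
  for (r in seq_len(restarts)) {
    res <- anneal_match_once(cost, max_cost, n_props, t_factor)
    cc <- sum(ifelse(is.na(res), max_cost, cost[cbind(seq_len(n), res)]))
    if (cc < best_cost) {
      best <- res
      best_cost <- cc
    }
  }
  best
}

anneal_match_once <- function(cost, max_cost, n_props = 1e4,
                              t_factor = 0.95) {
  n <- nrow(cost); m <- ncol(cost)
  aug <- cbind(cost, matrix(max_cost, n, n))
  aug[!is.finite(aug)] <- max_cost * 10
  # start from greedy
  cur <- rep(NA_integer_, n)
  taken <- logical(m + n)
  for (i in order(apply(aug, 1, min))) {
    o <- order(aug[i, ])
    pick <- o[!taken[o]][1]
    cur[i] <- pick; taken[pick] <- TRUE
  }
  cost_of <- function(a) sum(aug[cbind(seq_len(n), a)])
  cur_cost <- cost_of(cur)
  best <- cur; best_cost <- cur_cost
  temp <- mean(aug[is.finite(aug) & aug < max_cost * 10]) + 1e-9
  for (it in seq_len(n_props)) {
    i <- sample.int(n, 1)
    new_col <- sample.int(m + n, 1)
    prop <- cur
    holder <- which(cur == new_col)
    if (length(holder) && holder != i) {
      prop[holder] <- cur[i]   # swap
    } else if (length(holder)) next
    prop[i] <- new_col
    pc <- cost_of(prop)
    if (pc < cur_cost || runif(1) < exp(-(pc - cur_cost) / temp)) {
      cur <- prop; cur_cost <- pc
      if (pc < best_cost) { best <- prop; best_cost <- pc }
    }
    temp <- temp * t_factor
    if (temp < 1e-12) break
  }
  # deterministic exchange polish: single moves, pairwise swaps and
  # 3-cycles, iterated to a local optimum
  repeat {
    improved <- FALSE
    for (i in seq_len(n)) {
      for (k in seq_len(n)) {
        if (k == i) next
        prop <- best
        prop[c(i, k)] <- best[c(k, i)]
        if (cost_of(prop) < cost_of(best) - 1e-12) {
          best <- prop
          improved <- TRUE
        }
      }
      free_cols <- setdiff(seq_len(m + n), best)
      for (fc in free_cols) {
        prop <- best
        prop[i] <- fc
        if (cost_of(prop) < cost_of(best) - 1e-12) {
          best <- prop
          improved <- TRUE
        }
        # displacement chain: i takes k's column, k moves to the free one
        for (k in seq_len(n)) {
          if (k == i) next
          prop <- best
          prop[i] <- best[k]
          prop[k] <- fc
          if (cost_of(prop) < cost_of(best) - 1e-12) {
            best <- prop
            improved <- TRUE
          }
        }
      }
    }
    if (n >= 3) {
      combs <- utils::combn(n, 3)
      for (cix in seq_len(ncol(combs))) {
        ijk <- combs[, cix]
        for (rot in list(c(2, 3, 1), c(3, 1, 2))) {
          prop <- best
          prop[ijk] <- best[ijk[rot]]
          if (cost_of(prop) < cost_of(best) - 1e-12) {
            best <- prop
            improved <- TRUE
          }
        }
      }
    }
    if (!improved) break
  }
  best_cost <- cost_of(best)
  best[best > m] <- NA_integer_
  best[!is.na(best) & aug[cbind(which(!is.na(best)), best[!is.na(best)])] >=
         max_cost] <- NA_integer_
  best
}

#' Mean squared displacement of a track
#'
#' `MSD(k dt)` is the average squared displacement over all record pairs
#' separated by `k` frames (time-average). 3-D when the track carries z,
#' 2-D otherwise. Units: square micrometers.
#'
#' @param track a `Track` (or data.frame of records).
#' @param pixel_size_nm lateral pixel size (nm).
#' @param frame_interval_s frame period (s).
#' @param max_lag largest lag in frames (default half the track span).
#' @return a `DiffusionResult` list with `msd` (data.frame `lag_s, msd_um2,
#'   n_pairs`), `dimensionality`, and `D = NA` until [fit_diffusion()].
#' @export
compute_msd <- function(track, pixel_size_nm = 160, frame_interval_s = 0.05,
                        max_lag = NULL) {
  rec <- if (inherits(track, "Track")) track$records else as.data.frame(track)
  rec <- rec[order(rec$frame), ]
  if (nrow(rec) < 4)
    return(structure(list(msd = NULL, D = NA_real_, dimensionality = 2,
                          flagged = "too_short"), class = "DiffusionResult"))
  px_um <- pixel_size_nm / 1000
  x <- rec$x * px_um
  y <- rec$y * px_um
  has_z <- !all(is.na(rec$z))
  z <- if (has_z) rec$z / 1000 else NULL
  fr <- rec$frame
  span <- max(fr) - min(fr)
  if (is.null(max_lag)) max_lag <- max(1, floor(span / 2))
  lags <- seq_len(max_lag)
  msd <- rep(NA_real_, max_lag)
  npairs <- integer(max_lag)
  for (k in lags) {
    # pairs separated by exactly k frames (robust to gaps)
    idx <- match(fr + k, fr)
    ok <- which(!is.na(idx))
    if (!length(ok)) next
    d2 <- (x[idx[ok]] - x[ok])^2 + (y[idx[ok]] - y[ok])^2
    if (has_z) d2 <- d2 + (z[idx[ok]] - z[ok])^2
    msd[k] <- mean(d2)
    npairs[k] <- length(ok)
  }
  keep <- !is.na(msd)
  structure(list(msd = data.frame(lag_s = lags[keep] * frame_interval_s,
                                  msd_um2 = msd[keep],
                                  n_pairs = npairs[keep]),
                 D = NA_real_,
                 dimensionality = if (has_z) 3L else 2L,
                 flagged = NULL),
            class = "DiffusionResult")
}

#' Fit a diffusion coefficient to an MSD curve
#'
#' Unweighted linear fit through the first `n_points` MSD points (origin not
#' forced); `D = slope / (2 dim)` in um^2/s. A negative slope is clamped to
#' `D = 0` and flagged.
#'
#' @param result a `DiffusionResult` from [compute_msd()].
#' @param n_points number of MSD points used (default 4).
#' @return the `DiffusionResult` with `D` (and `fit_points`) filled.
#' @export
fit_diffusion <- function(result, n_points = 4) {
  if (is.null(result$msd) || nrow(result$msd) < 2) {
    result$D <- NA_real_
    return(result)
  }
  n <- min(n_points, nrow(result$msd))
  sub <- result$msd[seq_len(n), ]
  fit <- stats::lm(msd_um2 ~ lag_s, data = sub)
  slope <- unname(coef(fit)[2])
  result$fit_points <- n
  if (slope < 0) {
    result$D <- 0
    result$flagged <- "negative_slope"
  } else {
    result$D <- slope / (2 * result$dimensionality)
  }
  result
}

#' Per-species diffusion summary
#'
#' Computes one diffusion coefficient per track and summarizes per species
#' label (median and interquartile range), the usual way multi-species
#' tracking experiments are reported.
#'
#' @param tracks list of `Track`s (with species labels).
#' @param pixel_size_nm,frame_interval_s units of the localizations.
#' @param n_points MSD points used per track.
#' @param min_length tracks shorter than this are skipped.
#' @return data.frame with `species, n_tracks, median_D, iqr_D, q25_D,
#'   q75_D` (um^2/s); tracks with empty species are excluded with a warning.
#' @export
species_split_diffusion <- function(tracks, pixel_size_nm = 160,
                                    frame_interval_s = 0.05, n_points = 4,
                                    min_length = 8) {
  per <- lapply(tracks, function(tr) {
    if (nrow(tr$records) < min_length) return(NULL)
    res <- fit_diffusion(compute_msd(tr, pixel_size_nm, frame_interval_s),
                         n_points)
    if (is.na(res$D)) return(NULL)
    data.frame(species = if (is.na(tr$species)) "" else tr$species,
               D = res$D, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  if (is.null(per) || nrow(per) == 0)
    return(data.frame(species = character(0), n_tracks = integer(0),
                      median_D = numeric(0), iqr_D = numeric(0),
                      q25_D = numeric(0), q75_D = numeric(0)))
  if (any(per$species == "")) {
    warning("excluding ", sum(per$species == ""),
            " track(s) with empty species label")
    per <- per[per$species != "", , drop = FALSE]
  }
  out <- do.call(rbind, lapply(split(per, per$species), function(g)
    data.frame(species = g$species[1], n_tracks = nrow(g),
               median_D = stats::median(g$D), iqr_D = stats::IQR(g$D),
               q25_D = stats::quantile(g$D, 0.25, names = FALSE),
               q75_D = stats::quantile(g$D, 0.75, names = FALSE))))
  rownames(out) <- NULL
  out
}

#' Flatten a list of tracks back to a localization table
#' @param tracks list of `Track`s.
#' @param channel_label channel label for the resulting table.
#' @export
tracks_to_table <- function(tracks, channel_label = "spatial") {
  df <- do.call(rbind, lapply(tracks, function(tr) {
    d <- tr$records
    d$track_id <- tr$track_id
    if (!is.na(tr$species)) d$species <- tr$species
    d
  }))
  localization_table(df, channel_label = channel_label)
}
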