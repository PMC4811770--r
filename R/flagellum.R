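## Dual-view flagellar analysis: channel registration, centerline tracking,
## arc-length intensity sampling, region-resolved FRET time series and
## logistic kinetics of the midpiece vs principal-piece response.

#' Dual-view movie container
#'
#' @param donor,acceptor 3D arrays `[rows, cols, frames]` of the two
#'   emission channels (same shape).
#' @param pixel_size_um Pixel size, µm/px.
#' @param frame_rate_hz Acquisition rate, Hz (1 Hz nominal).
#' @param droplet Optional droplet annotation: matrix `[frames, 2]` of
#'   (row, col) positions, or a single length-2 vector reused for all
#'   frames.
#' @return A `dualview_movie` object.
#' @export
dualview_movie <- function(donor, acceptor, pixel_size_um,
                           frame_rate_hz = 1, droplet = NULL) {
  if (!identical(dim(donor), dim(acceptor)))
    stop_domain("donor and acceptor stacks must have identical shape")
  if (frame_rate_hz <= 0) stop_domain("frame_rate_hz must be > 0")
  if (!is.null(droplet) && is.null(dim(droplet)))
    droplet <- matrix(droplet, nrow = dim(donor)[3], ncol = 2, byrow = TRUE)
  structure(list(donor = donor, acceptor = acceptor,
                 pixel_size_um = pixel_size_um,
                 frame_rate_hz = frame_rate_hz, droplet = droplet),
            class = "dualview_movie")
}

## -- registration ------------------------------------------------------------

## FFT cross-correlation between two equally sized matrices; returns the
## translation (drow, dcol) of `moving` relative to `fixed` with parabolic
## sub-pixel refinement, plus a normalized peak quality.
xcorr_shift <- function(fixed, moving) {
  a <- fixed - mean(fixed); b <- moving - mean(moving)
  fa <- fft(a); fb <- fft(b)
  cc <- Re(fft(fa * Conj(fb), inverse = TRUE))
  n <- dim(cc)
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  wrap <- function(i, len) ifelse(i - 1 > len / 2, i - 1 - len, i - 1)
  ## parabolic interpolation on the circular neighborhood of the peak
  sub <- function(i, len, vals) {
    denom <- vals[1] - 2 * vals[2] + vals[3]
    d <- if (denom != 0) 0.5 * (vals[1] - vals[3]) / denom else 0
    wrap(i, len) + max(min(d, 0.5), -0.5)
  }
  circ <- function(i, len) ((i - 1) %% len) + 1
  vr <- cc[circ(pk[1] + c(-1, 0, 1), n[1]), pk[2]]
  vc <- cc[pk[1], circ(pk[2] + c(-1, 0, 1), n[2])]
  quality <- max(cc) / length(cc) /
    (sqrt(sum(a^2) * sum(b^2)) + .Machine$double.eps)
  ## positive shift means `moving` content sits at larger index than `fixed`
  c(drow = -unname(sub(pk[1], n[1], vr)),
    dcol = -unname(sub(pk[2], n[2], vc)),
    quality = unname(quality))
}

## Bilinear sampling of matrix `img` at (row, col) positions; out-of-bounds
## points give NA.
bilinear_sample <- function(img, row, col) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(row); c0 <- floor(col)
  fr <- row - r0; fc <- col - c0
  ok <- r0 >= 1 & c0 >= 1 & r0 + 1 <= nr & c0 + 1 <= nc
  out <- rep(NA_real_, length(row))
  if (any(ok)) {
    i00 <- cbind(r0[ok], c0[ok]);     i01 <- cbind(r0[ok], c0[ok] + 1)
    i10 <- cbind(r0[ok] + 1, c0[ok]); i11 <- cbind(r0[ok] + 1, c0[ok] + 1)
    out[ok] <- img[i00] * (1 - fr[ok]) * (1 - fc[ok]) +
      img[i01] * (1 - fr[ok]) * fc[ok] +
      img[i10] * fr[ok] * (1 - fc[ok]) +
      img[i11] * fr[ok] * fc[ok]
  }
  ## exact grid points on the far edges
  edge <- !ok & row >= 1 & col >= 1 & row <= nr & col <= nc &
    (abs(row - round(row)) < 1e-9) & (abs(col - round(col)) < 1e-9)
  out[edge] <- img[cbind(round(row[edge]), round(col[edge]))]
  out
}

## Translate an image by (drow, dcol) using bilinear interpolation;
## uncovered border pixels are NA-filled then replaced by the nearest value.
shift_image <- function(img, drow, dcol) {
  nr <- nrow(img); nc <- ncol(img)
  g <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  v <- bilinear_sample(img, g$r + drow, g$c + dcol)
  out <- matrix(v, nr, nc)
  if (anyNA(out)) {
    fill <- mean(out, na.rm = TRUE)
    out[is.na(out)] <- fill
  }
  out
}

#' Register the acceptor channel onto the donor channel
#'
#' Per-frame rigid translation estimated by FFT cross-correlation with
#' parabolic sub-pixel peak interpolation; the acceptor frame is then
#' resampled onto the donor grid.
#'
#' @param movie A [dualview_movie()].
#' @param min_quality Normalized correlation-peak quality below which a
#'   frame is flagged as unregistered (its shift is still applied).
#' @return The movie with acceptor frames resampled; per-frame shifts
#'   (`shifts`, a `[frames, 2]` matrix of (drow, dcol)) and a logical
#'   `registered` flag per frame attached as attributes.
#' @export
register_channels <- function(movie, min_quality = 0.1) {
  stopifnot(inherits(movie, "dualview_movie"))
  nt <- dim(movie$donor)[3]
  shifts <- matrix(0, nt, 2, dimnames = list(NULL, c("drow", "dcol")))
  okflag <- logical(nt)
  for (k in seq_len(nt)) {
    s <- xcorr_shift(movie$donor[, , k], movie$acceptor[, , k])
    shifts[k, ] <- s[1:2]
    okflag[k] <- s[["quality"]] >= min_quality
    if (any(s[1:2] != 0))
      movie$acceptor[, , k] <- shift_image(movie$acceptor[, , k],
                                           s[["drow"]], s[["dcol"]])
  }
  attr(movie, "shifts") <- shifts
  attr(movie, "registered") <- okflag
  movie
}

## -- centerline tracking -----------------------------------------------------

## Zhang-Suen thinning of a logical matrix, vectorized over shifted copies.
zhang_suen_thin <- function(bw) {
  pad <- function(m) {
    out <- matrix(FALSE, nrow(m) + 2, ncol(m) + 2)
    out[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
    out
  }
  m <- pad(bw)
  nr <- nrow(m); nc <- ncol(m)
  core_r <- 2:(nr - 1); core_c <- 2:(nc - 1)
  nbrs <- function(m) {
    ## clockwise from north: P2..P9
    list(p2 = m[core_r - 1, core_c],     p3 = m[core_r - 1, core_c + 1],
         p4 = m[core_r, core_c + 1],     p5 = m[core_r + 1, core_c + 1],
         p6 = m[core_r + 1, core_c],     p7 = m[core_r + 1, core_c - 1],
         p8 = m[core_r, core_c - 1],     p9 = m[core_r - 1, core_c - 1])
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p <- nbrs(m)
      bsum <- Reduce(`+`, p)
      ring <- list(p$p2, p$p3, p$p4, p$p5, p$p6, p$p7, p$p8, p$p9, p$p2)
      a <- 0
      for (i in 1:8) a <- a + (!ring[[i]] & ring[[i + 1]])
      cur <- m[core_r, core_c]
      if (step == 1)
        cond <- !(p$p2 & p$p4 & p$p6) & !(p$p4 & p$p6 & p$p8)
      else
        cond <- !(p$p2 & p$p4 & p$p8) & !(p$p2 & p$p6 & p$p8)
      del <- cur & bsum >= 2 & bsum <= 6 & a == 1 & cond
      if (any(del)) {
        tmp <- m[core_r, core_c]; tmp[del] <- FALSE
        m[core_r, core_c] <- tmp
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m[core_r, core_c]
}

## Longest geodesic path on an 8-connected pixel skeleton (double BFS).
## Returns an n x 2 matrix of (row, col) along the path.
skeleton_longest_path <- function(skel) {
  idx <- which(skel)
  if (length(idx) == 0) return(NULL)
  nr <- nrow(skel)
  id <- seq_along(idx)
  pos <- match(seq_len(length(skel)), idx)  # linear index -> node id (or NA)
  off <- c(-1, 1, -nr, nr, -nr - 1, -nr + 1, nr - 1, nr + 1)
  rowof <- ((idx - 1) %% nr) + 1
  neighbors <- function(node) {
    lin <- idx[node] + off
    ## guard row wrap-around at matrix edges
    r <- rowof[node]
    valid <- lin >= 1 & lin <= length(skel)
    dr <- abs(((lin - 1) %% nr) + 1 - r) <= 1
    lin <- lin[valid & dr]
    out <- pos[lin]
    out[!is.na(out)]
  }
  bfs <- function(src) {
    dist <- rep(-1L, length(id)); par <- rep(0L, length(id))
    dist[src] <- 0L
    queue <- src; head <- 1
    while (head <= length(queue)) {
      u <- queue[head]; head <- head + 1
      for (v in neighbors(u)) if (dist[v] < 0) {
        dist[v] <- dist[u] + 1L; par[v] <- u
        queue <- c(queue, v)
      }
    }
    list(dist = dist, par = par)
  }
  b1 <- bfs(1L)
  u <- which.max(b1$dist)
  b2 <- bfs(u)
  v <- which.max(b2$dist)
  path <- integer(0); cur <- v
  while (cur != 0) { path <- c(path, cur); cur <- b2$par[cur] }
  cbind(row = rowof[path], col = ((idx[path] - 1) %/% nr) + 1)
}

#' Flagellum centerline container
#'
#' @param points `n x 2` matrix of (row, col) pixel coordinates ordered
#'   base (head-proximal) to tip.
#' @param arc_length_um Cumulative arc length, µm, starting at 0.
#' @param droplet_s_um Arc-length position of the cytoplasmic droplet, µm.
#' @param pixel_size_um Pixel size used, µm/px.
#' @return A `flagellum_centerline` object.
#' @export
flagellum_centerline <- function(points, arc_length_um, droplet_s_um = NA,
                                 pixel_size_um = NA) {
  if (arc_length_um[1] != 0 || any(diff(arc_length_um) <= 0))
    stop_domain("arc_length_um must be strictly increasing from 0")
  chord <- sqrt(sum((points[nrow(points), ] - points[1, ])^2)) * pixel_size_um
  structure(list(points = points, arc_length_um = arc_length_um,
                 droplet_s_um = droplet_s_um, pixel_size_um = pixel_size_um,
                 chord_um = chord),
            class = "flagellum_centerline")
}

#' Track the flagellar centerline in a single frame
#'
#' Pipeline: intensity threshold (Otsu by default) -> largest connected
#' component -> morphological skeleton (Zhang-Suen thinning) -> longest
#' path -> orientation from the brighter (head/droplet) end -> smoothing
#' spline -> resampling at a fixed arc-length step.
#'
#' @param frame Single-channel image matrix.
#' @param pixel_size_um Pixel size, µm/px.
#' @param droplet_hint Optional (row, col) of the droplet; used to orient
#'   the centerline and locate the droplet along it.
#' @param threshold Intensity threshold; default Otsu.
#' @param step_um Resampling step along the arc, µm (default 0.5).
#' @param min_length_um Minimum acceptable flagellum length (default 10).
#' @param spline_df Degrees of freedom of the smoothing splines.
#' @return A [flagellum_centerline()].
#' @export
track_centerline <- function(frame, pixel_size_um, droplet_hint = NULL,
                             threshold = NULL, step_um = 0.5,
                             min_length_um = 10, spline_df = 20) {
  rng <- range(frame)
  if (diff(rng) == 0) stop_domain("tracking failure: blank frame")
  scaled <- (frame - rng[1]) / diff(rng)
  if (is.null(threshold)) threshold <- EBImage::otsu(scaled)
  bw <- scaled > threshold
  if (!any(bw)) stop_domain("tracking failure: nothing above threshold")
  ## largest connected component
  lab <- EBImage::bwlabel(bw)
  sizes <- tabulate(lab[lab > 0])
  bw <- lab == which.max(sizes)
  skel <- zhang_suen_thin(bw)
  path <- skeleton_longest_path(skel)
  if (is.null(path) || nrow(path) < 3)
    stop_domain("tracking failure: no usable skeleton")
  raw_len <- sum(sqrt(rowSums(diff(path)^2))) * pixel_size_um
  if (raw_len < min_length_um)
    stop_domain(sprintf(
      "tracking failure: longest component is %.1f um (< %.1f um)",
      raw_len, min_length_um))

  ## orient base -> tip
  k <- min(5, nrow(path))
  if (!is.null(droplet_hint)) {
    d_head <- sum((path[1, ] - droplet_hint)^2)
    d_tail <- sum((path[nrow(path), ] - droplet_hint)^2)
    if (d_tail < d_head) path <- path[nrow(path):1, , drop = FALSE]
  } else {
    bright_head <- mean(frame[path[seq_len(k), , drop = FALSE]])
    bright_tail <- mean(frame[path[nrow(path) - seq_len(k) + 1, , drop = FALSE]])
    if (bright_tail > bright_head) path <- path[nrow(path):1, , drop = FALSE]
  }

  ## smooth and resample at uniform arc length
  u <- c(0, cumsum(sqrt(rowSums(diff(path)^2))))
  df <- min(spline_df, nrow(path) - 1)
  sp_r <- smooth.spline(u, path[, 1], df = df)
  sp_c <- smooth.spline(u, path[, 2], df = df)
  uf <- seq(0, max(u), length.out = max(10 * nrow(path), 200))
  rf <- predict(sp_r, uf)$y; cf <- predict(sp_c, uf)$y
  s_px <- c(0, cumsum(sqrt(diff(rf)^2 + diff(cf)^2)))
  s_um <- s_px * pixel_size_um
  targets <- seq(0, max(s_um), by = step_um)
  pts <- cbind(row = approx(s_um, rf, xout = targets)$y,
               col = approx(s_um, cf, xout = targets)$y)

  ## droplet position along the arc
  droplet_s <- NA_real_
  if (!is.null(droplet_hint)) {
    d2 <- (pts[, 1] - droplet_hint[1])^2 + (pts[, 2] - droplet_hint[2])^2
    droplet_s <- targets[which.min(d2)]
  } else {
    prof <- bilinear_sample(frame, pts[, 1], pts[, 2])
    sm <- stats::filter(prof, rep(1 / 5, 5), sides = 2)
    droplet_s <- targets[which.max(ifelse(is.na(sm), -Inf, sm))]
  }
  flagellum_centerline(pts, targets, droplet_s, pixel_size_um)
}

#' Sample channel intensities along a centerline
#'
#' Bilinear interpolation of an image at the centerline points; points
#' falling outside the frame are returned as `NA` (masked, never zero).
#'
#' @param centerline A [flagellum_centerline()].
#' @param img Image matrix (one channel, one frame).
#' @return Data frame with `s_um` and `intensity`.
#' @export
sample_along <- function(centerline, img) {
  v <- bilinear_sample(img, centerline$points[, 1], centerline$points[, 2])
  data.frame(s_um = centerline$arc_length_um, intensity = v)
}

## -- region kinetics ---------------------------------------------------------

region_windows <- function(droplet_s, total_s, window_um = 20,
                           offset_um = 5) {
  mp <- c(max(0, droplet_s - offset_um - window_um),
          max(0, droplet_s - offset_um))
  pp <- c(min(total_s, droplet_s + offset_um),
          min(total_s, droplet_s + offset_um + window_um))
  shortened <- (mp[2] - mp[1] < window_um - 1e-9) ||
    (pp[2] - pp[1] < window_um - 1e-9)
  if (shortened)
    warning(structure(
      class = c("fq_shortened_window", "warning", "condition"),
      list(message = "region window truncated at the flagellum end",
           call = NULL)))
  list(midpiece = mp, principal_piece = pp)
}

#' Region-resolved FRET time series from a dual-view movie
#'
#' For each frame: track the flagellum (or reuse a reference centerline),
#' sample both channels along the arc, compute the bleed-through-corrected
#' ratio per arc position, and average (mean and SD) within two 20-µm
#' windows placed `offset_um` from the droplet on the head side (midpiece)
#' and tip side (principal piece). Each region trace is finally normalized
#' to its pre-stimulus baseline.
#'
#' @param movie A [dualview_movie()] (register first if channels are
#'   misaligned).
#' @param beta Bleed-through coefficient (default 0.69).
#' @param window_um Region window length along the arc, µm (default 20).
#' @param offset_um Distance of each window from the droplet, µm
#'   (5–10 µm; default 5).
#' @param baseline_frames Number of initial frames defining the baseline
#'   (default 30).
#' @param tracking `"per_frame"` re-tracks every frame; `"reference"`
#'   tracks the first frame once and reuses that centerline.
#' @return List with `midpiece` and `principal_piece` data frames
#'   (`time_s`, `R`, `sd`), the window definitions, and the per-frame
#'   droplet arc positions.
#' @export
region_fret_timeseries <- function(movie, beta = 0.69, window_um = 20,
                                   offset_um = 5, baseline_frames = 30,
                                   tracking = c("per_frame", "reference")) {
  stopifnot(inherits(movie, "dualview_movie"))
  tracking <- match.arg(tracking)
  nt <- dim(movie$donor)[3]
  px <- movie$pixel_size_um
  times <- (seq_len(nt) - 1) / movie$frame_rate_hz

  hint_for <- function(k)
    if (!is.null(movie$droplet)) movie$droplet[k, ] else NULL
  ref <- NULL
  mp <- pp <- matrix(NA_real_, nt, 2)
  droplet_s <- rep(NA_real_, nt)
  win1 <- NULL
  for (k in seq_len(nt)) {
    cl <- if (tracking == "reference" && !is.null(ref)) ref else
      track_centerline(movie$donor[, , k], px, droplet_hint = hint_for(k))
    if (tracking == "reference" && is.null(ref)) ref <- cl
    droplet_s[k] <- cl$droplet_s_um
    win <- withCallingHandlers(
      region_windows(cl$droplet_s_um, max(cl$arc_length_um), window_um,
                     offset_um),
      fq_shortened_window = function(w)
        if (k > 1) invokeRestart("muffleWarning"))
    if (k == 1) win1 <- win
    d <- sample_along(cl, movie$donor[, , k])$intensity
    a <- sample_along(cl, movie$acceptor[, , k])$intensity
    r <- suppressWarnings(fret_ratio(d, a, beta))
    s <- cl$arc_length_um
    for (rg in c("midpiece", "principal_piece")) {
      sel <- s >= win[[rg]][1] & s <= win[[rg]][2] & !is.na(r)
      m <- if (any(sel)) c(mean(r[sel]), sd(r[sel])) else c(NA, NA)
      if (rg == "midpiece") mp[k, ] <- m else pp[k, ] <- m
    }
  }
  norm <- function(m) {
    base <- mean(m[seq_len(min(baseline_frames, nt)), 1], na.rm = TRUE)
    data.frame(time_s = times, R = m[, 1] / base, sd = m[, 2] / abs(base))
  }
  list(midpiece = norm(mp), principal_piece = norm(pp),
       windows = win1, droplet_s_um = droplet_s)
}

#' Fit logistic response kinetics to a normalized region trace
#'
#' Fits the four-parameter logistic
#' \deqn{y(t) = A_2 + (A_1 - A_2) / (1 + (t/x_0)^p)}
#' (initial plateau `A1`, final plateau `A2`, half-rise time `x0`, slope
#' exponent `p`). A trace with no resolvable rise is returned with the
#' `degenerate` flag set (`A1` = `A2` = trace mean) instead of a spurious
#' half-rise time.
#'
#' @param time_s Time points, s (first point may be 0).
#' @param y Normalized ratio trace.
#' @param min_amplitude Minimal |A2 - A1| (in trace units) below which the
#'   trace is declared degenerate; default 4 trace SDs of the first 10%.
#' @return A `logistic_fit` object (`A1`, `A2`, `x0_s`, `p`).
#' @export
fit_logistic_kinetics <- function(time_s, y, min_amplitude = NULL) {
  ok <- !is.na(y)
  t <- time_s[ok]; yy <- y[ok]
  if (length(yy) < 6) stop_domain("need >= 6 samples")
  nbase <- max(3, length(yy) %/% 10)
  if (is.null(min_amplitude))
    min_amplitude <- max(4 * sd(yy[seq_len(nbase)]), 1e-9)
  a1_0 <- mean(yy[seq_len(nbase)])
  a2_0 <- mean(tail(yy, nbase))
  if (abs(a2_0 - a1_0) < min_amplitude || diff(range(yy)) == 0) {
    est <- list(A1 = mean(yy), A2 = mean(yy), x0_s = NA_real_, p = NA_real_)
    return(new_fq_fit("logistic_fit", est, converged = TRUE,
                      degenerate = TRUE,
                      message = "no resolvable rise; plateau-only fit"))
  }
  model <- function(p)
    p[["A2"]] + (p[["A1"]] - p[["A2"]]) /
      (1 + (t / exp(p[["log_x0"]]))^exp(p[["log_p"]]))
  half <- (a1_0 + a2_0) / 2
  cross <- t[which.min(abs(yy - half))]
  par0 <- c(A1 = a1_0, A2 = a2_0,
            log_x0 = log(max(cross, t[2], 1e-6)), log_p = log(4))
  res <- fq_nlsLM(function(p) yy - model(p), par0, what = "logistic fit")
  se <- fq_lm_se(res)
  x0 <- exp(res$par[["log_x0"]]); pw <- exp(res$par[["log_p"]])
  est <- list(A1 = res$par[["A1"]], A2 = res$par[["A2"]], x0_s = x0, p = pw)
  ses <- list(A1 = se[["A1"]], A2 = se[["A2"]],
              x0_s = x0 * se[["log_x0"]], p = pw * se[["log_p"]])
  new_fq_fit("logistic_fit", est, ses, rss = res$deviance, converged = TRUE,
             degenerate = FALSE, data = data.frame(time_s = t, y = yy))
}

#' @export
predict.logistic_fit <- function(object, time_s = NULL, ...) {
  e <- object$estimate
  if (isTRUE(object$degenerate)) {
    if (is.null(time_s)) time_s <- 0
    return(rep(e$A1, length(time_s)))
  }
  if (is.null(time_s)) time_s <- object$data$time_s
  e$A2 + (e$A1 - e$A2) / (1 + (time_s / e$x0_s)^e$p)
}

#' Average fitted kinetics across cells
#'
#' Evaluates each cell's fitted logistic on a common time grid and returns
#' the pointwise mean and SD per region, the population summary used to
#' compare midpiece and principal-piece response kinetics.
#'
#' @param fits Named list per cell; each element a list with `midpiece`
#'   and `principal_piece` `logistic_fit` objects (>= 2 cells).
#' @param time_s Common time grid, s.
#' @return List per region: data frame with `time_s`, `mean`, `sd`.
#' @export
average_kinetics <- function(fits, time_s) {
  if (length(fits) < 2) stop_domain("need >= 2 cells")
  regions <- c("midpiece", "principal_piece")
  for (f in fits)
    if (!all(regions %in% names(f)))
      stop_domain("each cell must provide midpiece and principal_piece fits")
  out <- lapply(regions, function(rg) {
    curves <- vapply(fits, function(f) predict(f[[rg]], time_s),
                     numeric(length(time_s)))
    data.frame(time_s = time_s,
               mean = rowMeans(curves),
               sd = apply(curves, 1, sd))
  })
  names(out) <- regions
  out
}
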