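#' Canonical run designs for spatial and face-part mapping
#'
#' Constructs the timing and geometry of one mapping run. Two paradigms are
#' supported: `"spatial"`, a horizontal bar (1.1 d.v.a. high on a 10 d.v.a.
#' vertical extent) traversing the vertical meridian, and `"face"`, a sampling
#' window (one-ninth of the face image) traversing a normalized chin-to-hairline
#' face space. Both run six 32-s trials in the fixed order
#' down, up, blank, up, down, blank, preceded by dummy volumes that are
#' discarded during preprocessing.
#'
#' All geometry is expressed in normalized stimulus coordinates `u` in
#' \[0, 1\], with `u = 0` the top of the mapped space (5 d.v.a. above fixation;
#' hairline) and `u = 1` the bottom (5 d.v.a. below fixation; chin). The
#' aperture position advances every `update_period` TRs by `step_size`
#' normalized units; the printed step sizes do not exactly span the full
#' space over the 15 updates of a sweep, and the design honors the step size
#' and start edge rather than forcing the end point.
#'
#' The rapid identity flicker (5 frames on, 5 frames off at a 60 Hz refresh,
#' i.e. 6 Hz) is carried as metadata only; the neural model operates at TR
#' resolution.
#'
#' @param kind `"spatial"` or `"face"`.
#' @param overrides named list of fields to override (must be declared fields).
#' @return An object of class `run_design`: a list with fields `kind`, `tr`,
#'   `trial_sequence`, `trial_duration`, `n_dummy`, `refresh_rate`,
#'   `frames_on`, `frames_off`, `aperture_height`, `step_size`,
#'   `update_period`, `space_edges`.
#' @examples
#' d <- make_run_design("spatial")
#' total_volumes(d)   # 202
#' flicker_hz(d)      # 6
#' @export
make_run_design <- function(kind = c("spatial", "face"), overrides = list()) {
  if (!is.character(kind) || length(kind) != 1L || !kind %in% c("spatial", "face"))
    stop("unknown design kind: ", paste(deparse(substitute(kind)), collapse = ""))
  base <- list(
    kind           = kind,
    tr             = 1,
    trial_sequence = c("down", "up", "blank", "up", "down", "blank"),
    trial_duration = 32,
    n_dummy        = 10L,
    refresh_rate   = 60,
    frames_on      = 5L,
    frames_off     = 5L,
    update_period  = 2L
  )
  if (kind == "spatial") {
    # bar 1.1 d.v.a. high, step 0.55 d.v.a., on a 10 d.v.a. extent
    base$aperture_height <- 0.11
    base$step_size       <- 0.055
    base$space_edges     <- c(u0 = "5 d.v.a. above fixation", u1 = "5 d.v.a. below fixation")
  } else {
    base$aperture_height <- 1 / 9
    base$step_size       <- 1 / 18
    base$space_edges     <- c(u0 = "hairline", u1 = "chin")
  }
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(base))
    if (length(bad)) stop("unknown design field(s): ", paste(bad, collapse = ", "))
    base[names(overrides)] <- overrides
  }
  if (!is.numeric(base$tr) || base$tr <= 0) stop("tr must be positive")
  if (!is.numeric(base$trial_duration) || base$trial_duration <= 0)
    stop("trial_duration must be positive")
  if (base$aperture_height <= 0 || base$aperture_height >= 1)
    stop("aperture_height must be in (0, 1)")
  if (base$step_size <= 0 || base$step_size >= 1)
    stop("step_size must be in (0, 1)")
  structure(base, class = "run_design")
}

#' @rdname make_run_design
#' @param design a `run_design`.
#' @export
active_volumes <- function(design) {
  as.integer(round(length(design$trial_sequence) * design$trial_duration / design$tr))
}

#' @rdname make_run_design
#' @export
total_volumes <- function(design) design$n_dummy + active_volumes(design)

#' @rdname make_run_design
#' @export
flicker_hz <- function(design) {
  design$refresh_rate / (design$frames_on + design$frames_off)
}

#' @export
print.run_design <- function(x, ...) {
  cat(sprintf("<run_design: %s>\n", x$kind))
  cat(sprintf("  TR %g s; trials [%s] x %g s; %d dummy volumes (total %d)\n",
              x$tr, paste(x$trial_sequence, collapse = ", "),
              x$trial_duration, x$n_dummy, total_volumes(x)))
  cat(sprintf("  aperture height %.4f, step %.4f per %d TR(s); flicker %g Hz\n",
              x$aperture_height, x$step_size, x$update_period, flicker_hz(x)))
  invisible(x)
}

# aperture positions (interval [lo, hi] in u) for one down sweep,
# one row per TR of the trial
sweep_positions <- function(design) {
  trs_per_trial <- as.integer(round(design$trial_duration / design$tr))
  n_pos <- trs_per_trial %/% design$update_period
  k <- rep(seq_len(n_pos) - 1L, each = design$update_period)
  length(k) <- trs_per_trial            # pad (NA) if trial not divisible; not the default
  if (anyNA(k)) k[is.na(k)] <- n_pos - 1L
  lo <- k * design$step_size
  cbind(lo = lo, hi = lo + design$aperture_height)
}

#' Build the time-by-space aperture occupancy matrix for a run
#'
#' Rasterizes the aperture schedule of a run design onto `n_bins` equal bins
#' spanning normalized stimulus space \[0, 1\]. Each active row holds the
#' fractional occupancy of each bin (analytic interval/bin overlap, so edge
#' bins carry partial weights); rows within blank trials are all zero. The
#' down sweep starts with the aperture's leading (upper) edge at `u = 0`; the
#' up sweep is the exact time-reversal of the down sweep's position schedule.
#'
#' @param design a `run_design` from [make_run_design()].
#' @param n_bins number of spatial bins (>= 20). Default 200 (bin width
#'   0.005, matching the mu grid pitch of [default_mu_grid()]).
#' @return An object of class `aperture_matrix`: list with `weights`
#'   (T_active x n_bins matrix, entries in \[0, 1\]), `bin_centers`,
#'   `bin_width`, `kind`, and the originating `design`.
#' @examples
#' ap <- build_aperture(make_run_design("spatial"))
#' dim(ap$weights)  # 192 x 200
#' @export
build_aperture <- function(design, n_bins = 200L) {
  stopifnot(inherits(design, "run_design"))
  if (n_bins < 20L) stop("n_bins must be >= 20")
  bw <- 1 / n_bins
  if (design$aperture_height / bw < 2)
    stop("n_bins too small to resolve aperture (aperture spans < 2 bins)")
  edges <- seq(0, 1, length.out = n_bins + 1L)
  centers <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  pos_down <- sweep_positions(design)
  pos_up <- pos_down[rev(seq_len(nrow(pos_down))), , drop = FALSE]

  occupancy_rows <- function(pos) {
    # fractional overlap of [lo, hi] with each bin, per row
    t(vapply(seq_len(nrow(pos)), function(i) {
      lo <- pos[i, "lo"]; hi <- pos[i, "hi"]
      ov <- pmin(hi, edges[-1L]) - pmax(lo, edges[-(n_bins + 1L)])
      pmin(pmax(ov, 0) / bw, 1)
    }, numeric(n_bins)))
  }
  rows_down <- occupancy_rows(pos_down)
  rows_up <- occupancy_rows(pos_up)
  trs_per_trial <- as.integer(round(design$trial_duration / design$tr))
  blank <- matrix(0, trs_per_trial, n_bins)
  blocks <- lapply(design$trial_sequence, function(tt)
    switch(tt, down = rows_down, up = rows_up, blank = blank,
           stop("unknown trial label: ", tt)))
  weights <- do.call(rbind, blocks)
  dimnames(weights) <- NULL
  structure(list(weights = weights, bin_centers = centers, bin_width = bw,
                 kind = design$kind, design = design),
            class = "aperture_matrix")
}

#' @export
print.aperture_matrix <- function(x, ...) {
  cat(sprintf("<aperture_matrix: %s, %d TRs x %d bins (bin width %.4g)>\n",
              x$kind, nrow(x$weights), length(x$bin_centers), x$bin_width))
  invisible(x)
}

#' Convert between normalized stimulus units and degrees of visual angle
#'
#' The spatial mapping space spans 10 d.v.a. along the vertical meridian, with
#' `u = 0` at 5 d.v.a. above fixation and `u = 1` at 5 d.v.a. below, so
#' `dva = 5 - 10 u` (positive above fixation). Values outside \[0, 1\] are
#' permitted (the mu search grid extends beyond the stimulus edges).
#'
#' @param x numeric vector to convert.
#' @param direction `"u_to_dva"` or `"dva_to_u"`.
#' @return converted numeric vector.
#' @examples
#' norm_dva_convert(0, "u_to_dva")    # +5 (upper edge)
#' norm_dva_convert(0.5, "u_to_dva")  # 0 (fixation)
#' @export
norm_dva_convert <- function(x, direction = c("u_to_dva", "dva_to_u")) {
  direction <- match.arg(direction)
  if (direction == "u_to_dva") 5 - 10 * x else (5 - x) / 10
}

#' Write / read an aperture matrix as TSV with a JSON sidecar
#'
#' Rows are TRs and columns bins; the sidecar records bin centers, kind and
#' the design fields needed to rebuild the object.
#'
#' @param aperture an `aperture_matrix`.
#' @param path TSV path; the sidecar is written to `paste0(path, ".json")`.
#' @return `write_aperture`: `path`, invisibly. `read_aperture`: the
#'   reconstructed `aperture_matrix`.
#' @export
write_aperture <- function(aperture, path) {
  stopifnot(inherits(aperture, "aperture_matrix"))
  utils::write.table(aperture$weights, path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  side <- list(bin_centers = aperture$bin_centers, bin_width = aperture$bin_width,
               kind = aperture$kind,
               design = aperture$design[setdiff(names(aperture$design), "space_edges")])
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_aperture
#' @export
read_aperture <- function(path) {
  w <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(w) <- NULL
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  des <- side$design
  design <- make_run_design(des$kind,
                            overrides = des[setdiff(names(des), "kind")])
  structure(list(weights = w, bin_centers = side$bin_centers,
                 bin_width = side$bin_width, kind = side$kind, design = design),
            class = "aperture_matrix")
}
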