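# Synthetic-data generators: every input the pipeline needs, with known
# ground truth, produced in code. A single root seed fans out to per-stage
# child seeds so the stages stay independently reproducible.

.child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 48271L + k * 9973L) %% 2147483399L
}

#' Generate a swarm with a mode-specific radius distribution
#'
#' Samples wheel radii from the mode's truncated log-normal law (the
#' "fingerprint" of the actuation pattern), then derives bead count, mass
#' and rotation rate from the physics model. Deterministic under a seed.
#'
#' @param mode A [swarm_mode()] object or mode name.
#' @param n_wheels Number of wheels. Default 500.
#' @param params A `uw_params` object.
#' @param seed Optional RNG seed.
#' @param packing Bead-count estimate, `"default"` or `"hcp"`.
#' @return A `uw_swarm` with all wheels at x = 0.
#' @examples
#' sw <- gen_swarm("flipping", n_wheels = 100, seed = 1)
#' range(sw$wheels$R) * 1e6  # within [4.5, 20] um
#' @export
gen_swarm <- function(mode = "rolling", n_wheels = 500,
                      params = default_params(), seed = NULL,
                      packing = "default") {
  if (is.character(mode)) mode <- swarm_mode(mode)
  uw_check(inherits(mode, "uw_mode"), "mode must be a swarm_mode()")
  uw_check(n_wheels > 0, "n_wheels must be > 0")
  if (!is.null(seed)) set.seed(seed)
  d <- mode$dist
  R <- .rtrunc_lnorm(n_wheels, d$meanlog, d$sdlog, d$lower_um, d$upper_um) * 1e-6
  wheels <- data.frame(wheel_id = seq_len(n_wheels), R = R,
                       n = n_beads(R, params, packing = packing),
                       mass = wheel_mass(R, params, packing = packing),
                       omega = rotation_rate(R, params),
                       x = 0, alive = TRUE)
  uw_swarm(wheels, mode = mode, params = params)
}

#' Generate a branching network
#'
#' Builds a trunk-and-exits tree: a main channel with `n_branches - 1` turn
#' junctions, each offering a terminal exit branch, the trunk continuing to
#' a final bifurcation into the last two terminals. Segment lengths and
#' junction inclines are drawn uniformly from the given ranges; parallel
#' channel mouths are annotated at random turns. The named preset
#' `"mca6"` is a fixed, hand-laid six-terminal tree inspired by a middle
#' cerebral artery geometry, with 0.6 mm channel diameter and inclines
#' within -15 to +30 degrees over ~23 mm of arc.
#'
#' @param n_branches Number of terminal branches (>= 2). Default 6.
#' @param seed Optional RNG seed.
#' @param incline_range Junction incline range (deg). Default c(-30, 45).
#' @param seg_length Segment length range between junctions (m). Default
#'   2-5 mm.
#' @param parallel_prob Probability that a turn carries a parallel-channel
#'   annotation. Default 0.5.
#' @param channel_diameter Channel diameter (m). Default 6e-4.
#' @param preset `NULL` or `"mca6"` for the fixed six-branch tree.
#' @param target Target branch id. Default the first exit (`"br1"`).
#' @return A validated `uw_network`.
#' @export
gen_network <- function(n_branches = 6, seed = NULL,
                        incline_range = c(-30, 45),
                        seg_length = c(2e-3, 5e-3),
                        parallel_prob = 0.5, channel_diameter = 6e-4,
                        preset = NULL, target = "br1") {
  if (!is.null(preset)) {
    uw_check(identical(preset, "mca6"), "unknown preset", "uw_config_error")
    return(.mca6_network(target))
  }
  uw_check(n_branches >= 2, "need at least 2 terminal branches")
  uw_check(all(incline_range > -90 & incline_range < 90),
           "incline range must lie within (-90, 90)")
  if (!is.null(seed)) set.seed(seed)
  rphi <- function() stats::runif(1, incline_range[1], incline_range[2])
  rseg <- function() stats::runif(1, seg_length[1], seg_length[2])
  rows <- list()
  add <- function(id, branch, x, phi, kind, children = character(0),
                  par = numeric(0)) {
    rows[[length(rows) + 1L]] <<- list(id = id, branch = branch, x = x,
                                       phi_deg = phi, kind = kind,
                                       children = children,
                                       parallel_offsets = par)
  }
  n_turns <- n_branches - 1L
  x <- 0
  phi <- rphi()
  add("start", "trunk1", 0, phi, "waypoint")
  for (ti in seq_len(n_turns)) {
    x <- x + rseg()
    phi <- rphi()
    trunk <- paste0("trunk", ti)
    exit_br <- paste0("br", ti)
    if (ti < n_turns) {
      kids <- c(exit_br, paste0("trunk", ti + 1))
    } else {
      kids <- c(exit_br, paste0("br", ti + 1))
    }
    par <- if (stats::runif(1) < parallel_prob) x + rseg() / 2 else numeric(0)
    add(paste0("T", ti), trunk, x, phi, "turn", children = kids, par = par)
    # terminal exit branch: starts at the turn with the turn's incline
    xe <- x + rseg()
    add(paste0("br", ti, "_a"), exit_br, x, phi, "waypoint")
    add(paste0("br", ti, "_end"), exit_br, xe, rphi(), "terminal")
    if (ti == n_turns) {
      xe2 <- x + rseg()
      add(paste0("br", ti + 1, "_a"), paste0("br", ti + 1), x, phi, "waypoint")
      add(paste0("br", ti + 1, "_end"), paste0("br", ti + 1), xe2, rphi(),
          "terminal")
    } else {
      add(paste0("T", ti, "_cont"), paste0("trunk", ti + 1), x, phi, "waypoint")
    }
  }
  j <- data.frame(id = vapply(rows, `[[`, "", "id"),
                  branch = vapply(rows, `[[`, "", "branch"),
                  x = vapply(rows, `[[`, 0, "x"),
                  phi_deg = vapply(rows, `[[`, 0, "phi_deg"),
                  kind = vapply(rows, `[[`, "", "kind"),
                  stringsAsFactors = FALSE)
  j$children <- lapply(rows, `[[`, "children")
  j$parallel_offsets <- lapply(rows, `[[`, "parallel_offsets")
  uw_network(j, target = target, channel_diameter = channel_diameter)
}

# fixed six-terminal tree; arc positions in mm (converted), gentle inclines
# so a rolling swarm traverses it within the 10-minute cap
.mca6_network <- function(target = "br1") {
  mk <- function(id, branch, x_mm, phi, kind, children = character(0),
                 par_mm = numeric(0)) {
    list(id = id, branch = branch, x = x_mm * 1e-3, phi_deg = phi,
         kind = kind, children = children, parallel_offsets = par_mm * 1e-3)
  }
  rows <- list(
    mk("start", "trunk", 0, 0, "waypoint"),
    mk("w1", "trunk", 4, 5, "waypoint"),
    mk("T1", "trunk", 8, 10, "turn", c("br1", "t2"), par_mm = 9.0),
    mk("br1_a", "br1", 8, 10, "waypoint"),
    mk("br1_end", "br1", 11, 20, "terminal"),
    mk("t2_a", "t2", 8, 10, "waypoint"),
    mk("T2", "t2", 11, 0, "turn", c("br2", "t3")),
    mk("br2_a", "br2", 11, 0, "waypoint"),
    mk("br2_end", "br2", 14, -15, "terminal"),
    mk("t3_a", "t3", 11, 0, "waypoint"),
    mk("T3", "t3", 14, 15, "turn", c("br3", "t4"), par_mm = 14.8),
    mk("br3_a", "br3", 14, 15, "waypoint"),
    mk("br3_end", "br3", 17, 30, "terminal"),
    mk("t4_a", "t4", 14, 15, "waypoint"),
    mk("T4", "t4", 17, 5, "turn", c("br4", "t5")),
    mk("br4_a", "br4", 17, 5, "waypoint"),
    mk("br4_end", "br4", 20, -10, "terminal"),
    mk("t5_a", "t5", 17, 5, "waypoint"),
    mk("T5", "t5", 20, 0, "turn", c("br5", "br6"), par_mm = 21.0),
    mk("br5_a", "br5", 20, 0, "waypoint"),
    mk("br5_end", "br5", 23, 10, "terminal"),
    mk("br6_a", "br6", 20, 0, "waypoint"),
    mk("br6_end", "br6", 24, 20, "terminal"))
  j <- data.frame(id = vapply(rows, `[[`, "", "id"),
                  branch = vapply(rows, `[[`, "", "branch"),
                  x = vapply(rows, `[[`, 0, "x"),
                  phi_deg = vapply(rows, `[[`, 0, "phi_deg"),
                  kind = vapply(rows, `[[`, "", "kind"),
                  stringsAsFactors = FALSE)
  j$children <- lapply(rows, `[[`, "children")
  j$parallel_offsets <- lapply(rows, `[[`, "parallel_offsets")
  uw_network(j, target = target, channel_diameter = 6e-4)
}

#' Scan-pair generator specification
#'
#' @param shape Image dimensions `c(rows, cols)`. Default c(96, 128).
#' @param pixel_size Pixel size (m). Default 50e-6.
#' @param n_beads Total injected beads. Default 5000.
#' @param beads_per_count Ground-truth calibration (beads per intensity
#'   count). Default 5e-4.
#' @param signal_level Nominal per-pixel signal intensity. Default 20000.
#' @param background_mean Mean background intensity; drawn strictly below
#'   the 3600 threshold by default so thresholding removes it exactly.
#' @param noise `"poisson"` (default) for Poisson-distributed pixel values,
#'   `"none"` for exact construction.
#' @param seed Optional RNG seed.
#' @return A list of class `uw_scan_spec`.
#' @export
scan_spec <- function(shape = c(96, 128), pixel_size = 50e-6, n_beads = 5000,
                      beads_per_count = 5e-4, signal_level = 20000,
                      background_mean = 1200, noise = c("poisson", "none"),
                      seed = NULL) {
  noise <- match.arg(noise)
  uw_check(n_beads > 0 && beads_per_count > 0, "bead counts must be positive")
  uw_check(signal_level >= 3600 && signal_level <= 60000,
           "signal_level must lie in [3600, 60000]")
  structure(list(shape = shape, pixel_size = pixel_size, n_beads = n_beads,
                 beads_per_count = beads_per_count,
                 signal_level = signal_level,
                 background_mean = background_mean, noise = noise,
                 seed = seed),
            class = "uw_scan_spec")
}

# rectangular ROI layout: injection strip, trunk strip, branch blocks
.scan_rois <- function(shape, branch_names) {
  nr <- shape[1]; nc <- shape[2]
  blank <- matrix(FALSE, nr, nc)
  masks <- list()
  inj <- blank; inj[, 1:floor(nc * 0.15)] <- TRUE
  masks$injection <- inj
  trk <- blank; trk[, (floor(nc * 0.15) + 1):floor(nc * 0.45)] <- TRUE
  masks$trunk <- trk
  k <- length(branch_names)
  ncol_grid <- ceiling(k / 3)
  nrow_grid <- min(k, 3L)
  c0 <- floor(nc * 0.45)
  bw <- floor((nc - c0) / ncol_grid)
  bh <- floor(nr / nrow_grid)
  for (i in seq_len(k)) {
    gi <- (i - 1) %% nrow_grid
    gj <- (i - 1) %/% nrow_grid
    m <- blank
    r <- (gi * bh + 2):((gi + 1) * bh - 1)
    cc <- (c0 + gj * bw + 2):(c0 + (gj + 1) * bw - 1)
    m[r, cc] <- TRUE
    masks[[branch_names[i]]] <- m
  }
  uw_roiset(masks)
}

# deposit `counts` total intensity into pixels of `mask`, at ~level per pixel
.deposit <- function(px, mask, counts, level) {
  if (counts <= 0) return(px)
  idx <- which(mask)
  npix <- ceiling(counts / level)
  if (npix > length(idx))
    uw_stop("ROI too small for requested signal", "uw_config_error")
  use <- idx[seq_len(npix)]
  vals <- rep(level, npix)
  vals[npix] <- counts - level * (npix - 1)
  px[use] <- px[use] + vals
  px
}

#' Generate a matched pre/post fluorescence scan pair with ground truth
#'
#' The pre scan places the full injected bead signal in the injection ROI;
#' the post scan redistributes it according to per-branch delivered mass
#' fractions (for example from a [simulate_targeting()] result), with any
#' undelivered remainder left in the trunk ROI so total signal is conserved.
#' Pixel values get Poisson noise and a sub-threshold background, so the
#' quantification stage can be tested against exact ground truth.
#'
#' @param fractions Named numeric vector of per-branch mass fractions
#'   (names must be branch ROI names; sum <= 1).
#' @param spec A [scan_spec()].
#' @return A list: `pre`, `post` (`uw_scan`), `rois` (`uw_roiset`), `truth`
#'   (list with `fractions`, `n_beads`, `beads_per_count`,
#'   `total_intensity`).
#' @export
gen_scan_pair <- function(fractions, spec = scan_spec()) {
  uw_check(!is.null(names(fractions)) && all(nzchar(names(fractions))),
           "fractions must be named by branch")
  uw_check(all(fractions >= 0) && sum(fractions) <= 1 + 1e-12,
           "fractions must be nonnegative and sum to at most 1")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  rois <- .scan_rois(spec$shape, names(fractions))
  total_counts <- round(spec$n_beads / spec$beads_per_count)
  nr <- spec$shape[1]; nc <- spec$shape[2]
  pre <- .deposit(matrix(0, nr, nc), rois$injection, total_counts,
                  spec$signal_level)
  post <- matrix(0, nr, nc)
  for (b in names(fractions))
    post <- .deposit(post, rois[[b]], round(fractions[[b]] * total_counts),
                     spec$signal_level)
  rest <- total_counts - sum(post)
  post <- .deposit(post, rois$trunk, rest, spec$signal_level)
  noisify <- function(px) {
    sig <- px > 0
    if (spec$noise == "poisson" && any(sig))
      px[sig] <- stats::rpois(sum(sig), px[sig])
    if (spec$background_mean > 0) {
      bg <- stats::rpois(sum(!sig), spec$background_mean)
      px[!sig] <- pmin(bg, 3599)
    }
    pmin(px, 65535)
  }
  list(pre = uw_scan(noisify(pre), spec$pixel_size, "pre"),
       post = uw_scan(noisify(post), spec$pixel_size, "post"),
       rois = rois,
       truth = list(fractions = fractions, n_beads = spec$n_beads,
                    beads_per_count = spec$beads_per_count,
                    total_intensity = total_counts))
}

#' Generate a calibration scan with a known beads-per-count
#'
#' @param n_beads Beads present in the field. Default 200.
#' @param spec A [scan_spec()] (its `beads_per_count` is the ground truth).
#' @return A list: `scan` (`uw_scan`), `n_beads`, `beads_per_count`.
#' @export
gen_calibration_scan <- function(n_beads = 200, spec = scan_spec()) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  counts <- round(n_beads / spec$beads_per_count)
  nr <- spec$shape[1]; nc <- spec$shape[2]
  mask <- matrix(TRUE, nr, nc)
  px <- .deposit(matrix(0, nr, nc), mask, counts, spec$signal_level)
  sig <- px > 0
  if (spec$noise == "poisson") px[sig] <- stats::rpois(sum(sig), px[sig])
  bg <- stats::rpois(sum(!sig), spec$background_mean)
  px[!sig] <- pmin(bg, 3599)
  list(scan = uw_scan(pmin(px, 65535), spec$pixel_size, "calibration"),
       n_beads = n_beads, beads_per_count = spec$beads_per_count)
}

#' Delivered-mass fractions from a targeting result
#'
#' Maps a [simulate_targeting()] result onto per-branch fractions for
#' [gen_scan_pair()]: the delivered fraction goes to the target branch;
#' losses and residual stay in the trunk/untargeted regions (handled by the
#' generator's remainder rule).
#'
#' @param result A `uw_targeting_result`.
#' @param target Target branch name.
#' @return Named numeric vector of fractions.
#' @export
result_fractions <- function(result, target) {
  stats::setNames(result$efficiency, target)
}
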