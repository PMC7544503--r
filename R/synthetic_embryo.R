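# Kinematic generative model of head involution.
#
# The generator prescribes noise-free per-frame displacements for four cell
# populations and adds i.i.d. Gaussian positional jitter:
#
#   * pharynx: a central multi-ring cylinder (plus an anterior apex cell)
#     that translates posteriorly along the AP axis by `retraction_um` over
#     the window, with a mild radial contraction;
#   * interface neurons: a ventral shell hugging the pharynx; each frame
#     they receive `attachment` times the displacement of their nearest
#     pharyngeal cell (paired at the first frame) plus
#     `(1 - attachment)` times a slight anterior drift (the mutant
#     behavior);
#   * chain neurons: two mirror-image chains on the outer neuron shell
#     (an ellipse in the transverse plane) that move circumferentially
#     toward the ventral midline; each link follows its predecessor's
#     angular step lagged one frame scaled by `chain_cohesion`, the leader
#     follows the prescribed involution schedule scaled the same way, and
#     `(1 - chain_cohesion)` of the motion is replaced by anterior drift;
#   * amphid cells (bilateral static clusters), a dorsal hypodermis arch
#     and posterior interior filler cells, all ideally static, which crowd
#     the embryo so Voronoi neighborhoods behave as in a packed tissue.
#
# Coordinate convention: +x anterior, +y dorsal, +z embryo right; the
# midline is the plane z = 0. Output is calibrated (microns).

# fixed anatomical layout (microns)
GEOM <- list(
  ring_x = c(8, 20),          # AP extent of the pharyngeal cylinder
  ring_radius = 4,            # initial pharynx cylinder radius
  ring_contraction = 0.8,     # radial scale factor reached at the last frame
  apex_offset = 1.5,          # apex cell this far anterior of the first ring
  interface_radius_offset = 2.5,  # interface shell sits this far off the pharynx
  interface_x = c(11, 16),
  interface_half_angle = 45,  # degrees from the ventral pole
  shell_a_y = 10,             # neuron-shell ellipse semi-axis (dorsoventral)
  shell_a_z = 15,             # neuron-shell ellipse semi-axis (mediolateral)
  chain_x0 = 14, chain_dx = -0.45,  # AP stagger along each chain
  chain_spacing = 2.6,        # arc distance between chain nuclei (um)
  hypodermis_a_y = 12, hypodermis_a_z = 17,  # outer hypodermal shell
  amphid_center_x = 13, amphid_center_y = -2, amphid_center_z = 9.5,
  plug_x = c(-1, 8.5), plug_radius = 5,
  floor_x = c(-1, 9), floor_y = -8.5, floor_z = 2.8,  # ventral-cord region
  midshell_radius = 9, midshell_angle = c(50, 170),  # deg, interior filler
  midshell_x = c(8, 19),
  anterior_pole_x = 30,
  nucleus_radius = 1.5
)

# The transverse neuron-shell contour is a flat-bottomed superellipse
# |z/a_z|^4 + |y/a_y|^4 = 1 (mounted embryos flatten ventrally), traversed
# at constant arc-length speed. Returns lookup tables over the contour
# parameter for one side (z >= 0), from the ventral pole upward.
shell_contour <- function(a_y, a_z, n = 4, ngrid = 4001L) {
  phi <- seq(0, pi * 0.75, length.out = ngrid)
  y <- -a_y * sign(cos(phi)) * abs(cos(phi))^(2 / n)
  z <- a_z * abs(sin(phi))^(2 / n)
  seg <- sqrt(diff(y)^2 + diff(z)^2)
  s <- c(0, cumsum(seg))
  list(phi = phi, y = y, z = z, s = s)
}

contour_at <- function(ct, s_query) {
  s_query <- pmin(max(ct$s), pmax(0, s_query))
  y <- stats::approx(ct$s, ct$y, xout = s_query)$y
  z <- stats::approx(ct$s, ct$z, xout = s_query)$y
  cbind(y = y, z = z)
}

# arc-length position on the contour at which |z| equals gap/2; restricted
# to the ascending (sub-equatorial) branch where z is monotone in arc length
contour_s_at_halfgap <- function(ct, halfgap) {
  asc <- ct$phi <= pi / 2
  if (halfgap > max(ct$z[asc])) stop("config error: gap exceeds the embryo width")
  stats::approx(ct$z[asc], ct$s[asc], xout = halfgap)$y
}

#' Configuration of a synthetic involuting embryo
#'
#' Defaults encode the wild-type study conditions: an 18 um pharynx
#' retraction over a 65-frame window sampled every 75 s, full inter-tissue
#' attachment and intra-tissue cohesion, a 25 um initial separation between
#' the left and right chain leading edges, and 0.5 um per-frame positional
#' jitter. `mode = "mutant"` switches to the adhesion-deficient condition:
#' attachment and cohesion are abolished, neurons drift slightly anterior
#' instead of involuting, and the retraction magnitude and leading-edge
#' separation take the values observed in mutants (17 um and 28 um).
#'
#' @param mode `"wt"` or `"mutant"` preset; explicit arguments override the
#'   preset.
#' @param n_pharynx,n_interface,n_chain_per_side,n_amphid cell counts
#' @param n_hypodermis,n_other counts of static filler cells (dorsal
#'   hypodermal arch / posterior interior cells) that keep the embryo
#'   crowded
#' @param retraction_um total programmed pharynx translation (microns)
#' @param duration_frames window length in frames (>= 2)
#' @param frame_interval_s seconds per frame
#' @param attachment coupling of interface neurons to their pharyngeal
#'   partner, in `[0, 1]` (1 = wild type, 0 = mutant)
#' @param chain_cohesion coupling of each chain neuron to its predecessor,
#'   in `[0, 1]`
#' @param start_gap_um initial left-right separation of the chain leading
#'   edges (microns)
#' @param end_gap_um leading-edge separation at the end of involution
#'   (microns; default 2, two nuclei in contact at the midline)
#' @param noise_sd_um SD of the i.i.d. Gaussian positional jitter added per
#'   frame and axis
#' @param mutant_anterior_drift_um_per_frame anterior drift replacing
#'   coupled motion when attachment/cohesion are below 1
#' @param scripted_division optional `list(cell =, frame =)`: that cell is
#'   replaced from `frame` on by two daughters (suffix "a"/"p"), to
#'   exercise lineage concatenation
#' @param seed default RNG seed used by [simulate_embryo()]
#' @return list of class `synthetic_embryo_config`
#' @export
synthetic_embryo_config <- function(mode = c("wt", "mutant"),
                                    n_pharynx = 20, n_interface = 6,
                                    n_chain_per_side = 10, n_amphid = 8,
                                    n_hypodermis = 16, n_other = 44,
                                    retraction_um = NULL,
                                    duration_frames = 65,
                                    frame_interval_s = 75,
                                    attachment = NULL,
                                    chain_cohesion = NULL,
                                    start_gap_um = NULL,
                                    end_gap_um = 2,
                                    noise_sd_um = 0.5,
                                    mutant_anterior_drift_um_per_frame = 0.2,
                                    scripted_division = NULL,
                                    seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(retraction_um)) retraction_um <- if (mode == "wt") 18 else 17
  if (is.null(attachment)) attachment <- if (mode == "wt") 1 else 0
  if (is.null(chain_cohesion)) chain_cohesion <- if (mode == "wt") 1 else 0
  if (is.null(start_gap_um)) start_gap_um <- if (mode == "wt") 25 else 28
  cfg <- list(mode = mode, n_pharynx = n_pharynx, n_interface = n_interface,
              n_chain_per_side = n_chain_per_side, n_amphid = n_amphid,
              n_hypodermis = n_hypodermis, n_other = n_other,
              retraction_um = retraction_um, duration_frames = duration_frames,
              frame_interval_s = frame_interval_s, attachment = attachment,
              chain_cohesion = chain_cohesion, start_gap_um = start_gap_um,
              end_gap_um = end_gap_um, noise_sd_um = noise_sd_um,
              mutant_anterior_drift_um_per_frame = mutant_anterior_drift_um_per_frame,
              scripted_division = scripted_division, seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "synthetic_embryo_config")
}

validate_config <- function(cfg) {
  counts <- c(cfg$n_pharynx, cfg$n_interface, cfg$n_chain_per_side,
              cfg$n_amphid, cfg$n_hypodermis, cfg$n_other)
  if (any(counts < 0)) stop("config error: cell counts must be >= 0")
  if (cfg$n_pharynx > 0 && cfg$n_pharynx < 5) {
    stop("config error: n_pharynx must be 0 or >= 5 (apex + one ring)")
  }
  if (cfg$duration_frames < 2) stop("config error: duration_frames must be >= 2")
  if (cfg$attachment < 0 || cfg$attachment > 1 ||
      cfg$chain_cohesion < 0 || cfg$chain_cohesion > 1) {
    stop("config error: couplings must lie in [0, 1]")
  }
  if (cfg$retraction_um < 0 || cfg$noise_sd_um < 0) {
    stop("config error: retraction and noise must be >= 0")
  }
  if (cfg$start_gap_um < cfg$end_gap_um) {
    stop("config error: start_gap_um must be >= end_gap_um")
  }
  if (cfg$start_gap_um > 2 * GEOM$shell_a_z) {
    stop("config error: start_gap_um exceeds the embryo width (",
         2 * GEOM$shell_a_z, " um)")
  }
  if (cfg$frame_interval_s <= 0) stop("config error: frame_interval_s must be > 0")
  invisible(cfg)
}

#' Read/write a synthetic-embryo configuration as JSON
#' @param path JSON file path
#' @return the configuration
#' @export
read_embryo_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(synthetic_embryo_config, raw)
}

#' @rdname read_embryo_config
#' @param config a [synthetic_embryo_config()]
#' @export
write_embryo_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}

# noise-free cell layout at the first frame, with per-population metadata
initial_layout <- function(cfg) {
  g <- GEOM
  cells <- list()
  addc <- function(name, tissue, pos, extra = list()) {
    cells[[length(cells) + 1L]] <<- c(list(cell = name, tissue = tissue,
                                           x = pos[1], y = pos[2], z = pos[3]),
                                      extra)
  }
  # pharynx: apex + rings of 4
  if (cfg$n_pharynx > 0) {
    addc("phapex", "pharynx", c(g$ring_x[2] + g$apex_offset, 0, 0),
         list(radial = 0, angle = 0, axis_x = g$ring_x[2] + g$apex_offset))
    n_ring_cells <- cfg$n_pharynx - 1L
    n_rings <- ceiling(n_ring_cells / 4)
    ring_xs <- if (n_rings == 1) mean(g$ring_x) else
      seq(g$ring_x[1], g$ring_x[2], length.out = n_rings)
    k <- 0L
    for (ri in seq_len(n_rings)) {
      stagger <- if (ri %% 2 == 0) 22.5 else 0
      for (ai in 1:4) {
        if (k >= n_ring_cells) break
        k <- k + 1L
        ang <- (45 + 90 * (ai - 1) + stagger) * pi / 180
        addc(sprintf("ph%02d", k), "pharynx",
             c(ring_xs[ri], g$ring_radius * cos(ang), g$ring_radius * sin(ang)),
             list(radial = g$ring_radius, angle = ang, axis_x = ring_xs[ri]))
      }
    }
  }
  # interface neurons: ventral shell hugging the pharynx
  if (cfg$n_interface > 0) {
    r_int <- g$ring_radius + g$interface_radius_offset
    xs <- seq(g$interface_x[1], g$interface_x[2], length.out = cfg$n_interface)
    angs <- seq(-g$interface_half_angle, g$interface_half_angle,
                length.out = cfg$n_interface) * pi / 180
    for (k in seq_len(cfg$n_interface)) {
      addc(sprintf("int%02d", k), "neuron",
           c(xs[k], -r_int * cos(angs[k]), r_int * sin(angs[k])))
    }
  }
  # chain neurons on the flat-bottomed neuron-shell contour, mirrored
  # across z = 0, spaced by a fixed nuclear arc distance
  # the neuroectoderm sheet: per side, two anteroposterior columns of
  # circumferential chains; cell k has column (k-1) %% 2 and link
  # (k-1) %/% 2, so cells 1..4 are the leading-edge patch
  ct <- shell_contour(g$shell_a_y, g$shell_a_z)
  s_start <- contour_s_at_halfgap(ct, cfg$start_gap_um / 2)
  for (side in c("L", "R")) {
    sgn <- if (side == "L") -1 else 1
    for (k in seq_len(cfg$n_chain_per_side)) {
      col <- (k - 1L) %% 2L
      link <- (k - 1L) %/% 2L
      s_k <- s_start + link * g$chain_spacing
      yz <- contour_at(ct, s_k)
      addc(sprintf("cn%s%02d", side, k), "neuron",
           c(g$chain_x0 + 1.25 - 2.5 * col + link * g$chain_dx,
             yz[1, "y"], sgn * yz[1, "z"]),
           list(side = side, link = link, arc = s_k))
    }
  }
  # amphid: two static bilateral clusters on the lateral mid-shell
  if (cfg$n_amphid > 0) {
    offs <- rbind(c(0, 0, 0), c(1.6, 1.1, 0.3), c(0.2, 1.8, 1.4),
                  c(1.7, 0.1, 1.6), c(0.8, -1.2, 0.8), c(-0.9, 0.9, 1.1),
                  c(-1.1, -0.7, 0.2), c(0.4, 0.5, -1.5))
    nl <- ceiling(cfg$n_amphid / 2); nr <- cfg$n_amphid - nl
    for (k in seq_len(nl)) {
      o <- offs[(k - 1L) %% nrow(offs) + 1L, ]
      addc(sprintf("amL%02d", k), "amphid",
           c(g$amphid_center_x + o[1], g$amphid_center_y + o[2],
             -g$amphid_center_z - o[3]))
    }
    for (k in seq_len(nr)) {
      o <- offs[(k - 1L) %% nrow(offs) + 1L, ]
      addc(sprintf("amR%02d", k), "amphid",
           c(g$amphid_center_x + o[1], g$amphid_center_y + o[2],
             g$amphid_center_z + o[3]))
    }
  }
  # dorsal hypodermal arch on the outer shell
  if (cfg$n_hypodermis > 0) {
    ncol_arch <- min(8L, cfg$n_hypodermis)
    nrows <- ceiling(cfg$n_hypodermis / ncol_arch)
    xs <- if (nrows == 1) 13 else seq(9, 18, length.out = nrows)
    for (k in seq_len(cfg$n_hypodermis)) {
      col <- (k - 1L) %% ncol_arch
      row <- (k - 1L) %/% ncol_arch
      phi <- (100 + col * 160 / max(1L, ncol_arch - 1L)) * pi / 180
      addc(sprintf("hyp%02d", k), "hypodermis",
           c(xs[row + 1L], -g$hypodermis_a_y * cos(phi),
             g$hypodermis_a_z * sin(phi)))
    }
  }
  # unscreened interior cells ("other"): a lateral/dorsal mid-shell between
  # the chain shell and the pharynx, a ventral sub-pharyngeal row, and a
  # posterior interior plug. They keep the embryo packed the way real head
  # tissue is, which is what makes Voronoi neighborhoods local.
  if (cfg$n_other > 0) {
    n_mid <- round(cfg$n_other * 0.41)
    n_floor <- round(cfg$n_other * 0.23)
    n_plug <- cfg$n_other - n_mid - n_floor
    k_all <- 0L
    if (n_mid > 0) {
      # mirrored left/right grid over (angle, x); both sides equally covered
      n_ang <- 5L
      for (k in seq_len(n_mid)) {
        s <- if (k %% 2 == 0) 1 else -1
        j <- (k - 1L) %/% 2L          # position index within a side
        col <- j %% n_ang
        row <- j %/% n_ang
        ang <- (g$midshell_angle[1] + col * diff(g$midshell_angle) /
                  (n_ang - 1L)) * pi / 180
        n_x <- max(1L, ceiling(ceiling(n_mid / 2) / n_ang))
        x <- g$midshell_x[1] + diff(g$midshell_x) * (row + 0.5) / n_x
        k_all <- k_all + 1L
        addc(sprintf("oth%02d", k_all), "other",
             c(x, -g$midshell_radius * cos(ang), s * g$midshell_radius * sin(ang)))
      }
    }
    if (n_floor > 0) {
      # ventral floor posterior of the interface patch: the nascent ventral
      # cord region; mirror-symmetric pairs across the midline
      nx <- ceiling(n_floor / 2)
      xs_f <- seq(g$floor_x[1], g$floor_x[2], length.out = nx)
      for (k in seq_len(n_floor)) {
        sgn <- if (k %% 2 == 0) 1 else -1
        x <- xs_f[(k - 1L) %/% 2L + 1L]
        k_all <- k_all + 1L
        addc(sprintf("oth%02d", k_all), "other",
             c(x, g$floor_y, sgn * g$floor_z))
      }
    }
    if (n_plug > 0) {
      for (k in seq_len(n_plug)) {
        x <- g$plug_x[1] + diff(g$plug_x) * (k - 0.5) / n_plug
        r <- g$plug_radius * sqrt((k - 0.5) / n_plug)
        a <- k * 2.399963
        k_all <- k_all + 1L
        addc(sprintf("oth%02d", k_all), "other", c(x, r * cos(a), r * sin(a)))
      }
    }
  }
  cells
}

#' Simulate a synthetic involuting embryo
#'
#' Integrates the kinematic update rules of the generative model (see
#' [synthetic_embryo_config()]) and returns a calibrated, labeled
#' [embryo_recording()] together with the generative ground truth. The same
#' `(config, seed)` pair always produces a bit-identical recording.
#'
#' @param config a [synthetic_embryo_config()]
#' @param seed RNG seed (defaults to the seed stored in the config)
#' @return list with elements `recording` (an [embryo_recording()] in
#'   microns) and `truth`: list with the designated `interface_set`, the
#'   interface-to-pharynx pairing (`interface_partner`), ordered chain cell
#'   names (`chain_left`, `chain_right`), the `leader_cells`, the
#'   `ventral_cluster` used for correlation analysis (leading four links
#'   per side), the realized start/end leading-edge gaps, the
#'   `expected_convergence` of the leader pair, and the noise-free
#'   trajectories (`ideal`)
#' @export
simulate_embryo <- function(config, seed = config$seed) {
  validate_config(config)
  cfg <- config
  g <- GEOM
  T_ <- cfg$duration_frames
  nstep <- T_ - 1L
  layout <- initial_layout(cfg)
  names(layout) <- vapply(layout, `[[`, character(1), "cell")
  ncell <- length(layout)
  if (ncell == 0L) stop("config error: embryo has no cells")

  pos <- array(NA_real_, dim = c(T_, ncell, 3),
               dimnames = list(NULL, names(layout), c("x", "y", "z")))
  for (j in seq_len(ncell)) {
    pos[1, j, ] <- c(layout[[j]]$x, layout[[j]]$y, layout[[j]]$z)
  }
  tissue <- vapply(layout, `[[`, character(1), "tissue")

  # pharynx kinematics: posterior translation + mild radial contraction.
  # The contraction accompanies retraction (apical constriction drives the
  # retraction), so its depth scales with the programmed retraction and
  # vanishes in a static embryo.
  dx_ph <- if (nstep > 0) -cfg$retraction_um / nstep else 0
  contraction_depth <- (1 - g$ring_contraction) * min(1, cfg$retraction_um / 18)
  radial_scale <- function(t) 1 - contraction_depth * (t - 1) / max(1L, nstep)
  ph_names <- names(tissue)[tissue == "pharynx"]
  ph_pos_at <- function(t) {  # ideal pharynx positions at frame t (1-based)
    out <- matrix(NA_real_, length(ph_names), 3, dimnames = list(ph_names, NULL))
    for (nm in ph_names) {
      li <- layout[[nm]]
      out[nm, ] <- c(li$axis_x + dx_ph * (t - 1),
                     li$radial * radial_scale(t) * cos(li$angle),
                     li$radial * radial_scale(t) * sin(li$angle))
    }
    out
  }

  # interface pairing: nearest pharynx cell at the first frame
  int_names <- grep("^int", names(layout), value = TRUE)
  partner <- character(0)
  if (length(int_names) && length(ph_names)) {
    ph1 <- ph_pos_at(1)
    partner <- vapply(int_names, function(nm) {
      p <- pos[1, nm, ]
      d2 <- rowSums(sweep(ph1, 2, p)^2)
      ph_names[which.min(d2)]
    }, character(1))
  }

  # chain schedule: constant arc-length speed along the shell contour
  ct <- shell_contour(g$shell_a_y, g$shell_a_z)
  s_start <- contour_s_at_halfgap(ct, cfg$start_gap_um / 2)
  s_end <- contour_s_at_halfgap(ct, cfg$end_gap_um / 2)
  n_travel <- max(1L, min(round(3600 / cfg$frame_interval_s), nstep))
  step_arc <- (s_start - s_end) / n_travel

  chain_info <- lapply(layout, function(li) li[c("side", "link", "arc")])
  arcs <- vapply(names(layout), function(nm) {
    if (!is.null(chain_info[[nm]]$arc)) chain_info[[nm]]$arc else NA_real_
  }, numeric(1))

  # per-cell drift directions and positional noise share one seeded stream.
  # Uncoupled cells drift slightly anterior, each along its own slowly
  # wandering bearing (anterior unit bias with AR(1) lateral jitter,
  # correlation time ~10 frames): detached neurons meander, they do not
  # hold a micrometer-coherent common vector for 80 minutes.
  drift_rho <- 0.9; drift_sd <- 1.5
  rng <- with_preserved_seed(seed, {
    u <- array(0, dim = c(ncell, max(1L, nstep), 2))
    eps <- array(stats::rnorm(ncell * max(1L, nstep) * 2),
                 dim = c(ncell, max(1L, nstep), 2))
    u[, 1, ] <- eps[, 1, ]
    if (nstep > 1) for (t in 2:nstep) {
      u[, t, ] <- drift_rho * u[, t - 1, ] + sqrt(1 - drift_rho^2) * eps[, t, ]
    }
    list(drift_u = u,
         noise = matrix(stats::rnorm(3L * ncell * T_, sd = 1), ncell * T_, 3))
  })
  drift_of <- function(nm, t) {
    j <- match(nm, names(layout))
    d <- c(1, drift_sd * rng$drift_u[j, t, ])
    cfg$mutant_anterior_drift_um_per_frame * d / sqrt(sum(d^2))
  }

  for (t in 1L:nstep) {            # step from frame t to t + 1
    ph_now <- if (length(ph_names)) ph_pos_at(t) else NULL
    ph_next <- if (length(ph_names)) ph_pos_at(t + 1L) else NULL
    for (j in seq_len(ncell)) {
      nm <- names(layout)[j]
      ti <- tissue[j]
      p_now <- pos[t, j, ]
      if (ti == "pharynx") {
        pos[t + 1L, j, ] <- ph_next[nm, ]
      } else if (grepl("^int", nm)) {
        dpart <- if (length(partner)) ph_next[partner[nm], ] - ph_now[partner[nm], ]
                 else c(0, 0, 0)
        pos[t + 1L, j, ] <- p_now + cfg$attachment * dpart +
          (1 - cfg$attachment) * drift_of(nm, t)
      } else if (grepl("^cn", nm)) {
        k <- chain_info[[nm]]$link
        sgn <- if (chain_info[[nm]]$side == "L") -1 else 1
        step_active <- (t - k) >= 1L && (t - k) <= n_travel
        ds <- if (step_active) cfg$chain_cohesion^(k + 1) * step_arc else 0
        arcs[nm] <- max(s_end, arcs[nm] - ds)
        yz <- contour_at(ct, arcs[nm])
        pos[t + 1L, j, ] <- c(p_now[1], yz[1, "y"], sgn * yz[1, "z"]) +
          (1 - cfg$chain_cohesion) * drift_of(nm, t)
      } else {
        pos[t + 1L, j, ] <- p_now   # amphid / hypodermis / other: static
      }
    }
  }

  ideal <- do.call(rbind, lapply(seq_len(ncell), function(j) {
    data.frame(time = 1L:T_, cell = names(layout)[j],
               x = pos[, j, 1], y = pos[, j, 2], z = pos[, j, 3])
  }))

  lineage <- character(0)
  labels <- stats::setNames(unname(tissue), names(layout))

  # optional scripted division to exercise lineage concatenation
  if (!is.null(cfg$scripted_division)) {
    sd_ <- cfg$scripted_division
    if (!sd_$cell %in% names(layout)) stop("config error: unknown division cell")
    f <- as.integer(sd_$frame)
    if (f <= 1L || f > T_) stop("config error: division frame outside window")
    mother <- ideal[ideal$cell == sd_$cell, , drop = FALSE]
    pre <- mother[mother$time < f, , drop = FALSE]
    post <- mother[mother$time >= f, , drop = FALSE]
    da <- post; da$cell <- paste0(sd_$cell, "a"); da$x <- da$x + 0.7
    dp <- post; dp$cell <- paste0(sd_$cell, "p"); dp$x <- dp$x - 0.7
    ideal <- rbind(ideal[ideal$cell != sd_$cell, , drop = FALSE], pre, da, dp)
    lineage[paste0(sd_$cell, "a")] <- sd_$cell
    lineage[paste0(sd_$cell, "p")] <- sd_$cell
    labels[paste0(sd_$cell, "a")] <- labels[sd_$cell]
    labels[paste0(sd_$cell, "p")] <- labels[sd_$cell]
  }
  ideal <- ideal[order(ideal$cell, ideal$time), , drop = FALSE]
  rownames(ideal) <- NULL

  obs <- ideal
  if (cfg$noise_sd_um > 0) {
    nz <- rng$noise
    if (nrow(nz) < nrow(ideal)) {  # scripted division added daughter rows
      extra <- with_preserved_seed(seed + 1L,
        matrix(stats::rnorm(3L * (nrow(ideal) - nrow(nz))), ncol = 3))
      nz <- rbind(nz, extra)
    }
    obs[, c("x", "y", "z")] <- ideal[, c("x", "y", "z")] +
      cfg$noise_sd_um * nz[seq_len(nrow(ideal)), ]
  }
  obs$radius <- g$nucleus_radius

  recording <- embryo_recording(
    obs, units = "um", frame_interval_s = cfg$frame_interval_s,
    xy_pixels_per_micron = 3, z_step_um = 1,
    labels = labels, lineage = lineage,
    anterior_pole = c(g$anterior_pole_x, 0, 0),
    midline_axis = c(0, 0, 1))

  chain_left <- sprintf("cnL%02d", seq_len(cfg$n_chain_per_side))
  chain_right <- sprintf("cnR%02d", seq_len(cfg$n_chain_per_side))
  ncl <- min(4L, cfg$n_chain_per_side)
  # ideal (noise-free) leading-edge separation per frame, for recovery tests
  ideal_gap <- rep(NA_real_, T_)
  if (cfg$n_chain_per_side > 0) {
    lead <- min(4L, cfg$n_chain_per_side)
    lcells <- sprintf("cnL%02d", seq_len(lead))
    rcells <- sprintf("cnR%02d", seq_len(lead))
    for (t in 1L:T_) {
      lp <- as.matrix(ideal[ideal$cell %in% lcells & ideal$time == t, c("x", "y", "z")])
      rp <- as.matrix(ideal[ideal$cell %in% rcells & ideal$time == t, c("x", "y", "z")])
      d2 <- outer(rowSums(lp^2), rowSums(rp^2), `+`) - 2 * lp %*% t(rp)
      ideal_gap[t] <- sqrt(max(0, min(d2)))
    }
  }

  truth <- list(
    config = cfg,
    interface_set = int_names,
    interface_partner = partner,
    chain_left = chain_left, chain_right = chain_right,
    leader_cells = if (cfg$n_chain_per_side > 0) c("cnL01", "cnR01") else character(0),
    ventral_cluster = c(chain_left[seq_len(ncl)], chain_right[seq_len(ncl)]),
    labels = labels,
    start_gap_um = cfg$start_gap_um,
    end_gap_um = cfg$end_gap_um,
    expected_convergence = cfg$start_gap_um - cfg$end_gap_um,
    retraction_um = cfg$retraction_um,
    n_travel_frames = n_travel,
    involution_window = c(1L, min(T_, n_travel + 1L)),
    ideal_gap = ideal_gap,
    ideal_min_gap = if (all(is.na(ideal_gap))) NA_real_ else min(ideal_gap),
    ideal = ideal)
  list(recording = recording, truth = truth)
}

# run expr with a local RNG state seeded by `seed`, restoring the caller's
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Synthetic image stack with a constant bright patch
#'
#' Test surface for [roi_mean_minus_background()]: a constant-background 3D
#' intensity array with an embedded constant rectangular patch.
#'
#' @param shape integer vector (ny, nx, nz)
#' @param patch_value,background_value intensities
#' @param patch_box integer vector (y0, y1, x0, x1, z0, z1), inclusive,
#'   within `shape`; a zero-size box (`NULL`) gives a pure background stack
#' @return 3D numeric array
#' @export
make_roi_fixture <- function(shape, patch_value, background_value, patch_box = NULL) {
  if (length(shape) != 3L || any(shape < 1)) stop("parameter error: shape must be (ny, nx, nz)")
  a <- array(background_value, dim = shape)
  if (!is.null(patch_box)) {
    b <- as.integer(patch_box)
    if (length(b) != 6L || b[1] > b[2] || b[3] > b[4] || b[5] > b[6] ||
        b[1] < 1L || b[3] < 1L || b[5] < 1L ||
        b[2] > shape[1] || b[4] > shape[2] || b[6] > shape[3]) {
      stop("parameter error: patch_box outside stack")
    }
    a[b[1]:b[2], b[3]:b[4], b[5]:b[6]] <- patch_value
  }
  a
}
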