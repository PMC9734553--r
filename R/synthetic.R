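## synthetic_data: toy HEAT-repeat solenoids, poly-PR sequences and
## scripted fixture trajectories, so the full pipeline runs without any
## download.
##
## The toy solenoid emulates the statistical structure of a karyopherin:
## tandem two-helix (A/B) repeats on a superhelical arc, B-helices facing
## the concave inner surface, negative charge concentrated on
## inner-facing B-helix beads, an optionally acidic mid linker, and toy
## binding-site classes placed the way the native partners bind (cargo
## and IBB on the inner surface, RanGTP on the acidic linker and inner
## residues, FG-Nups on the outer surface).

#' Specification of a toy HEAT-repeat solenoid
#'
#' @param n_repeats Number of HEAT repeats.
#' @param helix_len Residues per A- and per B-helix.
#' @param linker_len Residues in the intra-repeat (A to B) linker.
#' @param repeat_linker_len Residues in the inter-repeat (B to next A)
#'   linker.
#' @param radius Superhelical radius, nm.
#' @param pitch Axial rise per repeat, nm.
#' @param repeat_spacing Arc spacing between repeat centres, nm.
#' @param groove Radial distance between A- and B-helix axes, nm.
#' @param inner_density Probability that an inner-facing B-helix bead is
#'   negatively charged (D/E), in [0, 1].
#' @param outer_density Same for outer-facing A-helix beads.
#' @param acidic_linker Make the middle intra-repeat linker fully acidic
#'   (an H8-like insert).
#' @param aromatic_density Probability that a remaining helix bead is
#'   aromatic (F/Y/W).
#' @param site_sizes Named sizes of the toy binding-site classes.
#' @param seed Seed controlling all stochastic decoration.
#' @return List of class `solenoid_spec`.
#' @export
solenoid_spec <- function(n_repeats = 8L, helix_len = 8L, linker_len = 3L,
                          repeat_linker_len = 4L, radius = 3.2,
                          pitch = 0.45, repeat_spacing = 1.05,
                          groove = 1.4, inner_density = 0.6,
                          outer_density = 0.1, acidic_linker = TRUE,
                          aromatic_density = 0.05,
                          site_sizes = c(cargo = 12L, ibb = 8L,
                                         rangtp = 10L, fg_nup = 8L),
                          seed = 1L) {
  if (inner_density < 0 || inner_density > 1 ||
      outer_density < 0 || outer_density > 1 ||
      aromatic_density < 0 || aromatic_density > 1)
    stop("densities must lie in [0, 1]")
  if (n_repeats < 2L) stop("need at least 2 repeats")
  structure(as.list(environment()), class = "solenoid_spec")
}

#' Generate a toy HEAT-repeat solenoid
#'
#' Places Calpha beads on ideal helices (0.23 nm trace radius, 0.15 nm
#' rise, ~100 degrees per residue) arranged as antiparallel A/B pairs on
#' a superhelical arc, then decorates charges by surface facing: each
#' helix bead is classed inner- or outer-facing by the sign of its radial
#' offset from the helix axis relative to the solenoid axis. Negative
#' charges (D/E) are drawn with `inner_density` on inner-facing B beads
#' and `outer_density` on outer-facing A beads. The elastic network is
#' built over the whole (fully structured) solenoid.
#'
#' @param spec A `solenoid_spec`.
#' @return List: `model` (`cg_model`), `annotation`
#'   (`region_annotation`), `sites` (`binding_site_set`), `ncpr`, and a
#'   `bookkeeping` list with candidate/realized decoration counts.
#' @export
generate_toy_solenoid <- function(spec = solenoid_spec()) {
  stopifnot(inherits(spec, "solenoid_spec"))
  geom <- .solenoid_geometry(spec)
  n <- nrow(geom$pos)
  .with_seed(spec$seed, {
    seq <- rep("S", n)
    inner_B <- which(geom$label == "B" & geom$facing == "inner")
    outer_A <- which(geom$label == "A" & geom$facing == "outer")
    neg <- logical(n)
    neg[inner_B] <- runif(length(inner_B)) < spec$inner_density
    neg[outer_A] <- runif(length(outer_A)) < spec$outer_density
    acidic <- integer(0)
    if (spec$acidic_linker) {
      mid <- ceiling(spec$n_repeats / 2)
      acidic <- which(geom$label == "linker" & geom$heat == mid &
                      geom$intra)
      neg[acidic] <- TRUE
    }
    seq[neg] <- sample(c("D", "E"), sum(neg), replace = TRUE)
    helix_rest <- which(geom$label != "linker" & !neg)
    arom <- helix_rest[runif(length(helix_rest)) < spec$aromatic_density]
    seq[arom] <- sample(c("F", "Y", "W"), length(arom), replace = TRUE)
    neutral <- setdiff(which(!neg), arom)
    seq[neutral] <- sample(c("A", "L", "S", "T", "N", "Q", "V"),
                           length(neutral), replace = TRUE)

    model <- cg_model(paste(seq, collapse = ""), geom$pos,
                      structured = rep(TRUE, n), chain_id = "TOYKAP")
    ## toy binding sites: cargo + IBB inner surface, RanGTP acidic linker
    ## + inner, FG-Nup outer surface
    take <- function(pool, k) {
      if (length(pool) == 0L || k == 0L) return(integer(0))
      sort(pool[sample.int(length(pool), min(k, length(pool)))])
    }
    ss <- spec$site_sizes
    cargo <- take(inner_B, ss[["cargo"]])
    ibb <- take(setdiff(inner_B, cargo), ss[["ibb"]])
    rangtp <- sort(unique(c(acidic[seq_len(min(length(acidic), 6L))],
                            take(setdiff(inner_B, c(cargo, ibb)),
                                 max(0L, ss[["rangtp"]] -
                                         min(length(acidic), 6L))))))
    fg <- take(outer_A, ss[["fg_nup"]])
    sites <- binding_site_set(cargo, ibb, rangtp, fg, n_residues = n)
  })
  ann <- region_annotation(geom$spans$start, geom$spans$end,
                           geom$spans$heat, geom$spans$label)
  ## sanity: self-avoiding at a fraction of the excluded-volume diameter
  d <- as.matrix(dist(geom$pos))
  sep <- abs(row(d) - col(d))
  if (min(d[sep > 2]) < 0.42)
    stop("geometric self-collision in generated solenoid")
  list(model = model, annotation = ann, sites = sites,
       ncpr = compute_ncpr(model),
       bookkeeping = list(n_residues = n,
                          inner_B_candidates = length(inner_B),
                          outer_A_candidates = length(outer_A),
                          n_negative = sum(model$charges < 0),
                          n_acidic_linker = length(acidic),
                          realized_inner_density =
                            mean(model$charges[inner_B] < 0),
                          realized_outer_density =
                            if (length(outer_A))
                              mean(model$charges[outer_A] < 0) else NA))
}

## bead geometry of the solenoid: positions + per-bead labels/facing and
## annotation spans
.solenoid_geometry <- function(spec) {
  helix <- function(base, axis, e1, e2, n, phase = 0) {
    rise <- 0.15; rad <- 0.23; omega <- 100 * pi / 180
    t(vapply(seq_len(n) - 1L, function(m)
      base + m * rise * axis +
        rad * (cos(phase + m * omega) * e1 + sin(phase + m * omega) * e2),
      numeric(3)))
  }
  pos <- NULL
  label <- character(0); heat <- integer(0); facing <- character(0)
  intra <- logical(0)
  spans <- data.frame(start = integer(0), end = integer(0),
                      heat = integer(0), label = character(0))
  add_span <- function(n_new, lab, h) {
    s <- nrow_or0(pos) - n_new + 1L
    spans <<- rbind(spans, data.frame(start = s,
                                      end = nrow_or0(pos), heat = h,
                                      label = lab))
  }
  nrow_or0 <- function(x) if (is.null(x)) 0L else nrow(x)
  dphi <- spec$repeat_spacing / spec$radius
  hl <- spec$helix_len
  for (k in seq_len(spec$n_repeats)) {
    phi <- (k - 1L) * dphi
    z0 <- (k - 1L) * spec$pitch
    u <- c(cos(phi), sin(phi), 0)      # radial (outward)
    tg <- c(-sin(phi), cos(phi), 0)    # tangent
    baseA <- (spec$radius + spec$groove / 2) * u + c(0, 0, z0)
    baseB <- (spec$radius - spec$groove / 2) * u + c(0, 0, z0)
    ## radial offset of a bead from its (vertical) helix axis, along u:
    ## positive = pointing away from the solenoid axis = outer-facing
    radial_off <- function(H, axis_radius)
      H[, 1] * u[1] + H[, 2] * u[2] - axis_radius
    A <- helix(baseA, c(0, 0, 1), u, tg, hl)
    pos <- rbind(pos, A); add_span(hl, "A", k)
    facA <- ifelse(radial_off(A, spec$radius + spec$groove / 2) > 0,
                   "outer", "inner")
    label <- c(label, rep("A", hl)); heat <- c(heat, rep(k, hl))
    facing <- c(facing, facA); intra <- c(intra, rep(FALSE, hl))
    ## intra-repeat linker from A top to B top; B helix runs back down
    topA <- A[hl, ]
    B <- helix(baseB + c(0, 0, (hl - 1) * 0.15), c(0, 0, -1), u, tg, hl)
    nl <- spec$linker_len
    lk <- .linker_arc(topA, B[1, ], nl, bulge_dir = c(0, 0, 1))
    pos <- rbind(pos, lk); add_span(nl, "linker", k)
    label <- c(label, rep("linker", nl)); heat <- c(heat, rep(k, nl))
    facing <- c(facing, rep("none", nl)); intra <- c(intra, rep(TRUE, nl))
    pos <- rbind(pos, B); add_span(hl, "B", k)
    facB <- ifelse(radial_off(B, spec$radius - spec$groove / 2) > 0,
                   "outer", "inner")
    label <- c(label, rep("B", hl)); heat <- c(heat, rep(k, hl))
    facing <- c(facing, facB); intra <- c(intra, rep(FALSE, hl))
    ## inter-repeat linker from B bottom to next A bottom
    if (k < spec$n_repeats) {
      phi2 <- k * dphi
      u2 <- c(cos(phi2), sin(phi2), 0); tg2 <- c(-sin(phi2), cos(phi2), 0)
      nextA_base <- (spec$radius + spec$groove / 2) * u2 +
        c(0, 0, k * spec$pitch)
      nextA_first <- nextA_base + 0.23 * u2
      nrl <- spec$repeat_linker_len
      lk2 <- .linker_arc(B[hl, ], nextA_first, nrl,
                         bulge_dir = c(0, 0, -1))
      pos <- rbind(pos, lk2); add_span(nrl, "linker", k)
      label <- c(label, rep("linker", nrl)); heat <- c(heat, rep(k, nrl))
      facing <- c(facing, rep("none", nrl))
      intra <- c(intra, rep(FALSE, nrl))
    }
  }
  list(pos = pos, label = label, heat = heat, facing = facing,
       intra = intra, spans = spans)
}

## n interior beads between endpoints a and b along a gentle arc, bulged
## along `bulge_dir` (axially, away from the helix bodies)
.linker_arc <- function(a, b, n, bulge_dir = c(0, 0, 1)) {
  bulge <- 0.35 * sqrt(sum((b - a)^2))
  curve <- function(t) (1 - t) * a + t * b +
    bulge * sin(pi * t) * bulge_dir
  ## equal-arc-length interior points so backbone spacing is uniform
  tt <- seq(0, 1, length.out = 201)
  pts <- t(vapply(tt, curve, numeric(3)))
  s <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  want <- seq_len(n) / (n + 1) * s[length(s)]
  t(vapply(want, function(w) {
    k <- findInterval(w, s, all.inside = TRUE)
    frac <- (w - s[k]) / (s[k + 1] - s[k])
    pts[k, ] + frac * (pts[k + 1, ] - pts[k, ])
  }, numeric(3)))
}

#' Poly-PR sequence
#'
#' @param n Number of PR repeat units (>= 1).
#' @return The string "PR" repeated n times.
#' @export
generate_polypr_sequence <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n))
    stop("n must be an integer >= 1")
  paste(rep("PR", n), collapse = "")
}

#' Scripted fixture trajectory
#'
#' Builds a trajectory whose frames realize an exact contact pattern:
#' receptor beads sit on a 10 nm grid; a poly-PR bead scripted to touch
#' receptor bead j is placed 0.5 nm from it, all other poly-PR beads are
#' parked far (> 5 nm) from every receptor bead. The script is its own
#' closed-form oracle for the contact statistics.
#'
#' @param script List of frames; each frame is a 2-column matrix (or
#'   `NULL` for no contacts) of 1-based (pr_residue, kap_residue) pairs.
#' @param n_pr,n_kap Bead counts of the two chains.
#' @param dt Frame spacing, ps.
#' @return A `cg_trajectory` with open boundaries.
#' @export
generate_fixture_trajectory <- function(script, n_pr, n_kap, dt = 1) {
  nf <- length(script)
  if (nf < 1L) stop("empty script")
  kap_pos <- cbind(10 * (seq_len(n_kap) - 1L), 0, 0)
  frames <- array(NA_real_, c(n_pr + n_kap, 3, nf))
  for (f in seq_len(nf)) {
    sc <- script[[f]]
    pr_pos <- cbind(-50 - seq_len(n_pr) * 2, -50, 0)  # parked far away
    if (!is.null(sc) && length(sc)) {
      sc <- matrix(as.integer(sc), ncol = 2)
      if (any(sc[, 1] < 1L | sc[, 1] > n_pr |
              sc[, 2] < 1L | sc[, 2] > n_kap))
        stop("script indices outside chain ranges")
      if (anyDuplicated(sc[, 1]))
        stop("unrealizable script: a poly-PR residue cannot touch two ",
             "receptor beads at once in the fixture geometry")
      for (r in seq_len(nrow(sc))) {
        i <- sc[r, 1]; j <- sc[r, 2]
        ## 0.5 nm from kap bead j, fanned out so pr beads do not collide
        ang <- 2 * pi * i / (n_pr + 1)
        pr_pos[i, ] <- kap_pos[j, ] +
          0.5 * c(cos(ang), sin(ang), 0)
      }
    }
    frames[, , f] <- rbind(pr_pos, kap_pos)
  }
  structure(list(
    times = dt * (seq_len(nf) - 1),
    frames = frames, box = 0,
    chain_map = data.frame(bead = seq_len(n_pr + n_kap),
                           chain = rep(c(1L, 2L), c(n_pr, n_kap)),
                           role = rep(c("pr", "kap"), c(n_pr, n_kap))),
    chain_ids = c("PR", "KAP"), roles = c("pr", "kap"),
    sequences = c(PR = strrep("PR", ceiling(n_pr / 2)),
                  KAP = strrep("S", n_kap)),
    energy_log = NULL, equilibration_fraction = 0,
    config = NULL, final_state = NULL
  ), class = "cg_trajectory")
}
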