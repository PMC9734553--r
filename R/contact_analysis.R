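## contact_analysis: time-averaged contacts Ct, binding probability Pb,
## per-residue contact probabilities, contact sites, region-resolved
## Ncontact, overlap with native binding sites Nshared, NCPR regression.
##
## A pair contact is a (poly-PR bead, receptor bead) pair within the
## 1 nm cutoff (minimum-image distances); a residue is "in contact" when
## it participates in at least one pair contact. Both thresholds of the
## analysis are strict inequalities: a frame is bound when MORE than
## fraction*N_PR poly-PR residues are in contact, and a receptor residue
## is a contact site when its contact probability EXCEEDS the threshold.

.traj_roles <- function(traj) {
  cm <- traj$chain_map
  pr <- which(cm$role == "pr")
  kap <- which(cm$role == "kap")
  if (length(pr) == 0L) stop("trajectory has no poly-PR chain")
  if (length(kap) == 0L) stop("trajectory has no receptor chain")
  kap_chains <- unique(cm$chain[kap])
  if (length(kap_chains) > 1L)
    warning("multiple receptor chains; treating all as one receptor")
  list(pr = pr, kap = kap, pr_chains = unique(cm$chain[pr]))
}

#' Production frame indices after equilibration discard
#'
#' @param traj A `cg_trajectory`.
#' @param equilibration_fraction Fraction of frames discarded from the
#'   start; defaults to the value stored in the trajectory.
#' @return Integer frame indices.
#' @export
production_frames <- function(traj, equilibration_fraction = NULL) {
  nf <- dim(traj$frames)[3]
  frac <- if (is.null(equilibration_fraction))
    traj$equilibration_fraction else equilibration_fraction
  if (is.null(frac)) frac <- 0.2
  idx <- seq_len(nf)[seq_len(nf) > floor(frac * nf)]
  if (length(idx) == 0L) stop("zero production frames after discard")
  idx
}

#' Contacts in a single frame
#'
#' Counts (poly-PR bead, receptor bead) pairs within the cutoff under the
#' minimum-image convention and flags the residues involved.
#'
#' @param positions n x 3 matrix of all bead positions (nm).
#' @param chain_map Data frame with columns `chain` and `role`
#'   (`"pr"`/`"kap"`).
#' @param box Cubic box edge (nm), 0 for open boundaries.
#' @param cutoff Contact cutoff, nm (default 1.0).
#' @return List: `count` (pair contacts), `pr_flags`, `kap_flags`
#'   (logical, in-contact per residue of each role).
#' @export
frame_contacts <- function(positions, chain_map, box = 0, cutoff = 1.0) {
  pr <- which(chain_map$role == "pr")
  kap <- which(chain_map$role == "kap")
  if (length(pr) == 0L || length(kap) == 0L)
    stop("chain map must contain both a 'pr' and a 'kap' role")
  out <- cpp_frame_contacts(positions[pr, , drop = FALSE],
                            positions[kap, , drop = FALSE], box, cutoff)
  list(count = out$count, pr_flags = as.logical(out$flagsA),
       kap_flags = as.logical(out$flagsB))
}

## per-frame contact summaries over production frames
.contact_series <- function(traj, equilibration_fraction = NULL,
                            cutoff = 1.0) {
  roles <- .traj_roles(traj)
  idx <- production_frames(traj, equilibration_fraction)
  cm <- traj$chain_map
  npr <- length(roles$pr); nkap <- length(roles$kap)
  counts <- integer(length(idx))
  pr_flags <- matrix(FALSE, length(idx), npr)
  kap_flags <- matrix(FALSE, length(idx), nkap)
  for (f in seq_along(idx)) {
    fc <- frame_contacts(traj$frames[, , idx[f]], cm, traj$box, cutoff)
    counts[f] <- fc$count
    pr_flags[f, ] <- fc$pr_flags
    kap_flags[f, ] <- fc$kap_flags
  }
  list(frames = idx, counts = counts, pr_flags = pr_flags,
       kap_flags = kap_flags, pr_beads = roles$pr, kap_beads = roles$kap,
       pr_chain = cm$chain[roles$pr])
}

#' Time-averaged number of contacts Ct
#'
#' Mean over production frames of the per-frame contact count, with the
#' normalized value dividing by N_Kap * N_PR (receptor length times total
#' poly-PR length). `mode = "pairs"` (default) counts bead pairs;
#' `mode = "residues"` counts poly-PR residues in contact.
#'
#' @param traj A `cg_trajectory`.
#' @param equilibration_fraction Initial fraction of frames to discard.
#' @param cutoff Contact cutoff, nm.
#' @param mode Pair counting (default) or residue counting.
#' @return List: `Ct`, `Ct_normalized`, `n_kap`, `n_pr`, `per_frame`.
#' @export
time_averaged_contacts <- function(traj, equilibration_fraction = NULL,
                                   cutoff = 1.0,
                                   mode = c("pairs", "residues")) {
  mode <- match.arg(mode)
  cs <- .contact_series(traj, equilibration_fraction, cutoff)
  x <- if (mode == "pairs") cs$counts else rowSums(cs$pr_flags)
  n_kap <- length(cs$kap_beads); n_pr <- length(cs$pr_beads)
  Ct <- mean(x)
  list(Ct = Ct, Ct_normalized = Ct / (n_kap * n_pr), n_kap = n_kap,
       n_pr = n_pr, per_frame = x)
}

#' Binding probability Pb
#'
#' Fraction of production frames in which strictly more than
#' `fraction` of the poly-PR residues are within the cutoff of the
#' receptor. With several poly-PR copies each copy gets its own Pb and
#' `any` reports the fraction of frames with at least one bound copy.
#'
#' @inheritParams time_averaged_contacts
#' @param fraction Bound-fraction threshold (default 0.10, strict `>`).
#' @return List: `Pb` (first/only copy), `per_copy`, `any`, `n_frames`.
#' @export
binding_probability <- function(traj, fraction = 0.10,
                                equilibration_fraction = NULL,
                                cutoff = 1.0) {
  cs <- .contact_series(traj, equilibration_fraction, cutoff)
  copies <- unique(cs$pr_chain)
  per_copy <- vapply(copies, function(ch) {
    cols <- which(cs$pr_chain == ch)
    thr <- fraction * length(cols)
    mean(rowSums(cs$pr_flags[, cols, drop = FALSE]) > thr)
  }, numeric(1))
  names(per_copy) <- paste0("copy", seq_along(copies))
  bound_any <- rep(FALSE, length(cs$frames))
  for (ch in copies) {
    cols <- which(cs$pr_chain == ch)
    thr <- fraction * length(cols)
    bound_any <- bound_any |
      (rowSums(cs$pr_flags[, cols, drop = FALSE]) > thr)
  }
  list(Pb = unname(per_copy[1]), per_copy = per_copy,
       any = mean(bound_any), n_frames = length(cs$frames))
}

#' Per-residue contact probability profile
#'
#' For each receptor residue, the fraction of production frames in which
#' it contacts any poly-PR bead.
#'
#' @inheritParams time_averaged_contacts
#' @return Numeric vector over receptor residues, values in [0, 1].
#' @export
residue_contact_probability <- function(traj, equilibration_fraction = NULL,
                                        cutoff = 1.0) {
  cs <- .contact_series(traj, equilibration_fraction, cutoff)
  colMeans(cs$kap_flags)
}

#' Contact sites from a probability profile
#'
#' Receptor residues whose contact probability strictly exceeds the
#' threshold (default 0.10).
#'
#' @param profile Numeric profile from [residue_contact_probability()].
#' @param threshold Contact-site threshold (strict `>`).
#' @return Integer vector of 1-based residue indices.
#' @export
contact_sites <- function(profile, threshold = 0.10) {
  which(profile > threshold)
}

#' Region-resolved contact counts
#'
#' Number of contact sites falling in A-helix, B-helix and linker spans
#' of the annotation; sites outside every span are reported separately.
#'
#' @param sites Integer contact-site indices (1-based).
#' @param annotation A `region_annotation`.
#' @return List: `Ncontact` named counts (A, B, linker), `unannotated`.
#' @export
region_contact_counts <- function(sites, annotation) {
  ann <- as.data.frame(annotation)
  if (nrow(ann) > 1L) {
    o <- order(ann$start)
    if (any(ann$start[o][-1] <= ann$end[o][-nrow(ann)]))
      stop("overlapping spans")
  }
  lab <- rep(NA_character_, if (length(sites)) max(sites) else 0)
  counts <- c(A = 0L, B = 0L, linker = 0L)
  unann <- 0L
  for (s in sites) {
    hit <- which(ann$start <= s & s <= ann$end)
    if (length(hit)) counts[ann$label[hit[1]]] <-
        counts[ann$label[hit[1]]] + 1L
    else unann <- unann + 1L
  }
  list(Ncontact = counts, unannotated = unann)
}

#' Contact sites shared with native binding sites
#'
#' Per partner class, the size of the intersection between the poly-PR
#' contact-site set and the class's binding-site set. Classes without
#' known sites are reported as `NA` (the "(-)" convention), not zero.
#'
#' @param sites Integer contact-site indices.
#' @param binding_sites A `binding_site_set`.
#' @return Named integer vector (`cargo`, `ibb`, `rangtp`, `fg_nup`) with
#'   `NA` for absent classes.
#' @export
shared_binding_sites <- function(sites, binding_sites) {
  vapply(binding_sites, function(cl)
    if (length(cl) == 0L) NA_integer_ else length(intersect(sites, cl)),
    integer(1))
}

#' Half-standard-deviation uncertainty over blocks
#'
#' The error bar convention used throughout: half the sample standard
#' deviation of block means.
#'
#' @param blocks Numeric vector of per-block values (>= 2).
#' @return 0.5 * sd(blocks).
#' @export
scalar_uncertainty <- function(blocks) {
  if (length(blocks) < 2L) stop("need >= 2 blocks")
  0.5 * sd(blocks)
}

## split a per-frame series into `n_blocks` contiguous blocks and return
## block means (trailing remainder folded into the last block)
block_means <- function(x, n_blocks = 5L) {
  n <- length(x)
  if (n < n_blocks) n_blocks <- max(1L, n)
  cut_id <- pmin(ceiling(seq_along(x) / (n / n_blocks)), n_blocks)
  as.numeric(tapply(x, cut_id, mean))
}

#' Linear regression of normalized contacts on NCPR
#'
#' Ordinary least squares of normalized Ct against receptor NCPR with
#' the Pearson correlation, mirroring the linear contact/charge relation
#' across a receptor panel.
#'
#' @param ncpr Numeric vector of receptor NCPR values (>= 3 points).
#' @param ct_normalized Matching normalized Ct values.
#' @return List: `slope`, `intercept`, `correlation`.
#' @export
ncpr_contact_regression <- function(ncpr, ct_normalized) {
  if (length(ncpr) != length(ct_normalized) || length(ncpr) < 3L)
    stop("need >= 3 matched points")
  if (sd(ncpr) < 1e-14) stop("degenerate NCPR variance")
  slope <- sum((ncpr - mean(ncpr)) * (ct_normalized - mean(ct_normalized))) /
    sum((ncpr - mean(ncpr))^2)
  list(slope = slope,
       intercept = mean(ct_normalized) - slope * mean(ncpr),
       correlation = if (sd(ct_normalized) < 1e-14) 0 else
         cor(ncpr, ct_normalized))
}

#' Full contact analysis of a trajectory
#'
#' Computes Ct (raw and normalized), Pb, the residue contact-probability
#' profile, contact sites, region-resolved contact counts and overlap
#' with native binding sites, with half-standard-deviation uncertainties
#' from contiguous production blocks.
#'
#' @inheritParams time_averaged_contacts
#' @param annotation Optional `region_annotation`.
#' @param binding_sites Optional `binding_site_set`.
#' @param fraction Binding threshold fraction (strict `>`).
#' @param site_threshold Contact-site probability threshold (strict `>`).
#' @param n_blocks Number of uncertainty blocks.
#' @return List of class `contact_results`.
#' @export
analyze_trajectory <- function(traj, annotation = NULL,
                               binding_sites = NULL,
                               equilibration_fraction = NULL, cutoff = 1.0,
                               fraction = 0.10, site_threshold = 0.10,
                               mode = c("pairs", "residues"),
                               n_blocks = 5L) {
  mode <- match.arg(mode)
  cs <- .contact_series(traj, equilibration_fraction, cutoff)
  n_kap <- length(cs$kap_beads); n_pr <- length(cs$pr_beads)
  x <- if (mode == "pairs") cs$counts else rowSums(cs$pr_flags)
  Ct <- mean(x)
  copies <- unique(cs$pr_chain)
  bound <- rep(FALSE, length(cs$frames))
  per_copy <- numeric(0)
  for (ch in copies) {
    cols <- which(cs$pr_chain == ch)
    b <- rowSums(cs$pr_flags[, cols, drop = FALSE]) >
      fraction * length(cols)
    per_copy <- c(per_copy, mean(b))
    bound <- bound | b
  }
  profile <- colMeans(cs$kap_flags)
  sites <- contact_sites(profile, site_threshold)
  res <- list(
    Ct = Ct,
    Ct_normalized = Ct / (n_kap * n_pr),
    Ct_uncertainty = scalar_uncertainty(block_means(x, n_blocks)),
    Pb = per_copy[1],
    Pb_per_copy = per_copy,
    Pb_any = mean(bound),
    Pb_uncertainty = scalar_uncertainty(
      block_means(as.numeric(bound), n_blocks)),
    residue_profile = profile,
    contact_sites = sites,
    n_kap = n_kap, n_pr = n_pr,
    n_frames = length(cs$frames), mode = mode
  )
  if (!is.null(annotation)) {
    rc <- region_contact_counts(sites, annotation)
    res$Ncontact_by_region <- rc$Ncontact
    res$Ncontact_unannotated <- rc$unannotated
  }
  if (!is.null(binding_sites))
    res$Nshared_by_class <- shared_binding_sites(sites, binding_sites)
  class(res) <- "contact_results"
  res
}

#' @export
print.contact_results <- function(x, ...) {
  cat("contact_results over ", x$n_frames, " production frames (",
      x$mode, " mode)\n", sep = "")
  cat(sprintf("  Ct = %.2f +/- %.2f  (normalized %.3e)\n", x$Ct,
              x$Ct_uncertainty, x$Ct_normalized))
  cat(sprintf("  Pb = %.3f +/- %.3f\n", x$Pb, x$Pb_uncertainty))
  cat("  contact sites: ", length(x$contact_sites), "\n", sep = "")
  if (!is.null(x$Ncontact_by_region))
    cat("  Ncontact A/B/linker: ",
        paste(x$Ncontact_by_region, collapse = "/"), "\n", sep = "")
  if (!is.null(x$Nshared_by_class))
    cat("  Nshared: ", paste(names(x$Nshared_by_class),
                             x$Nshared_by_class, sep = "=",
                             collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Write contact results as TSV files plus a JSON summary
#'
#' @param results A `contact_results`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @export
write_contact_results <- function(results, dir, prefix = "contacts") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prof <- data.frame(residue = seq_along(results$residue_profile),
                     contact_probability = results$residue_profile)
  write.table(prof, file.path(dir, paste0(prefix, "_profile.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(contact_site = results$contact_sites),
              file.path(dir, paste0(prefix, "_sites.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- results[c("Ct", "Ct_normalized", "Ct_uncertainty", "Pb",
                    "Pb_any", "Pb_uncertainty", "n_kap", "n_pr",
                    "n_frames", "mode")]
  if (!is.null(results$Ncontact_by_region))
    summ$Ncontact_by_region <- as.list(results$Ncontact_by_region)
  if (!is.null(results$Nshared_by_class))
    summ$Nshared_by_class <- as.list(results$Nshared_by_class)
  writeLines(jsonlite::toJSON(summ, auto_unbox = TRUE, digits = NA,
                              na = "null"),
             file.path(dir, paste0(prefix, "_summary.json")))
  invisible(dir)
}
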