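## cg_builder: one-bead-per-amino-acid models of receptors and poly-PR.
##
## A cg_model holds one bead per residue at the Calpha position (nm), with
## charge/aromatic decoration, a structured/disordered mask, implicit
## backbone bonds between consecutive beads, and an elastic network of
## harmonic restraints between spatially proximal structured beads.

#' Construct a coarse-grained one-bead-per-residue model
#'
#' Beads carry the residue identity, position (nm), formal charge (e),
#' aromatic flag and a structured/disordered mask. Consecutive beads are
#' connected by backbone bonds of a single fixed rest length; structured
#' beads additionally carry an elastic network (see
#' [build_elastic_network()]) that preserves the tertiary fold.
#'
#' @param sequence One-letter amino-acid string (or character vector).
#' @param positions Numeric n x 3 matrix of bead positions in nm.
#' @param structured Logical vector: `TRUE` for beads resolved in the
#'   source structure (restrained by the elastic network), `FALSE` for
#'   modeled disordered beads.
#' @param elastic Data frame with columns `i`, `j`, `r0` (1-based bead
#'   indices, rest length nm), or `NULL` to build it with
#'   [build_elastic_network()].
#' @param chain_id Label for the chain.
#' @param backbone_r0 Backbone (virtual Calpha-Calpha) bond rest length, nm.
#' @param elastic_cutoff Distance cutoff (nm) used when `elastic` is built
#'   here.
#' @return An object of class `cg_model`.
#' @export
cg_model <- function(sequence, positions, structured = NULL, elastic = NULL,
                     chain_id = "chain", backbone_r0 = 0.38,
                     elastic_cutoff = 1.4) {
  seq <- .split_sequence(sequence)
  n <- length(seq)
  positions <- as.matrix(positions)
  if (!is.numeric(positions) || ncol(positions) != 3L || nrow(positions) != n)
    stop("positions must be a numeric ", n, " x 3 matrix")
  if (is.null(structured)) structured <- rep(TRUE, n)
  chem <- assign_bead_chemistry(seq)
  if (is.null(elastic))
    elastic <- build_elastic_network(positions, structured,
                                     cutoff = elastic_cutoff,
                                     backbone_r0 = backbone_r0)
  model <- structure(list(
    sequence = paste(seq, collapse = ""),
    positions = unname(positions),
    charges = chem$charges,
    aromatic = chem$aromatic,
    structured = as.logical(structured),
    backbone_r0 = backbone_r0,
    elastic = elastic,
    chain_id = chain_id
  ), class = "cg_model")
  validate_cg_model(model)
  model
}

.split_sequence <- function(sequence) {
  seq <- if (length(sequence) == 1L) strsplit(sequence, "")[[1]] else
    as.character(sequence)
  if (length(seq) == 0L) stop("empty sequence")
  seq
}

#' Validate cg_model invariants
#'
#' Checks field lengths, the charge alphabet, and that every elastic pair
#' connects two structured beads at its build-time rest length.
#'
#' @param model A `cg_model`.
#' @return The model, invisibly; errors on violation.
#' @export
validate_cg_model <- function(model) {
  n <- nchar(model$sequence)
  stopifnot(nrow(model$positions) == n,
            length(model$charges) == n,
            length(model$aromatic) == n,
            length(model$structured) == n)
  if (!all(model$charges %in% c(-1, 0, 1)))
    stop("charges must be in {-1, 0, +1}")
  el <- model$elastic
  if (nrow(el) > 0) {
    if (any(!model$structured[el$i]) || any(!model$structured[el$j]))
      stop("elastic pairs must connect structured beads")
    if (any(abs(el$j - el$i) < 2L))
      stop("elastic pairs must be separated by >= 2 in sequence")
  }
  invisible(model)
}

#' Charge and aromatic decoration of a sequence
#'
#' D and E beads carry charge -1, R and K carry +1, every other residue
#' (including histidine) is neutral; F, Y and W are flagged aromatic.
#'
#' @param sequence One-letter amino-acid string or character vector.
#' @return List with integer `charges` and logical `aromatic` per bead.
#' @export
assign_bead_chemistry <- function(sequence) {
  seq <- .split_sequence(sequence)
  bad <- which(!seq %in% .AA1)
  if (length(bad))
    stop("unknown residue code '", seq[bad[1]], "' at position ", bad[1])
  charges <- integer(length(seq))
  charges[seq %in% c("D", "E")] <- -1L
  charges[seq %in% c("R", "K")] <- 1L
  list(charges = charges, aromatic = seq %in% c("F", "Y", "W"))
}

#' Net charge per residue
#'
#' Total formal charge (elementary charge units) divided by sequence
#' length. Accepts a charge vector or a `cg_model`.
#'
#' @param x Numeric charge vector or `cg_model`.
#' @return NCPR, dimensionless.
#' @export
compute_ncpr <- function(x) {
  charges <- if (inherits(x, "cg_model")) x$charges else x
  if (length(charges) == 0L) stop("empty charge list")
  sum(charges) / length(charges)
}

#' Elastic network over structured beads
#'
#' All pairs of structured beads separated by at least two positions in
#' sequence and closer than `cutoff` in space become harmonic restraints
#' with rest length equal to the build-time distance. Consecutive beads are
#' handled by backbone bonds and never enter the network.
#'
#' @param positions n x 3 matrix, nm.
#' @param structured Logical mask of restrained beads.
#' @param cutoff Distance cutoff, nm; must exceed the backbone bond length.
#' @param backbone_r0 Backbone bond length used for the degeneracy check.
#' @return Data frame with columns `i`, `j` (1-based, i < j) and `r0` (nm).
#' @export
build_elastic_network <- function(positions, structured, cutoff = 1.4,
                                  backbone_r0 = 0.38) {
  if (cutoff <= backbone_r0)
    stop("elastic cutoff (", cutoff, " nm) must exceed the backbone bond ",
         "length (", backbone_r0, " nm): degenerate network")
  positions <- as.matrix(positions)
  idx <- which(as.logical(structured))
  if (length(idx) < 3L)
    return(data.frame(i = integer(0), j = integer(0), r0 = numeric(0)))
  pr <- cpp_elastic_pairs(positions, as.integer(idx - 1L), cutoff)
  data.frame(i = pr$i + 1L, j = pr$j + 1L, r0 = pr$r0)
}

#' Poly-PR chain model
#'
#' Builds the (PR)n dipeptide repeat protein: 2n beads, fully disordered,
#' alternating neutral proline and +1 arginine, so the net charge is +n and
#' the NCPR is +0.5 for every n. The initial conformation is a seeded
#' self-avoiding walk at backbone bond spacing.
#'
#' @param n_repeats Number of PR units (>= 1).
#' @param seed Seed for the initial conformation.
#' @param chain_id Chain label.
#' @param backbone_r0 Backbone bond length, nm.
#' @return A `cg_model` with empty elastic network.
#' @export
build_polypr <- function(n_repeats, seed = 1L, chain_id = "PR",
                         backbone_r0 = 0.38) {
  if (!is.numeric(n_repeats) || n_repeats < 1)
    stop("n_repeats must be >= 1")
  seq <- generate_polypr_sequence(n_repeats)
  pos <- .with_seed(seed, .self_avoiding_walk(nchar(seq), backbone_r0))
  cg_model(seq, pos, structured = rep(FALSE, nchar(seq)),
           elastic = data.frame(i = integer(0), j = integer(0),
                                r0 = numeric(0)),
           chain_id = chain_id, backbone_r0 = backbone_r0)
}

## free self-avoiding walk from the origin; min_sep guards self-clashes
.self_avoiding_walk <- function(n, bond, start = c(0, 0, 0),
                                min_sep = 0.36) {
  pos <- matrix(0, n, 3)
  pos[1, ] <- start
  for (t in seq_len(n - 1L)) {
    ok <- FALSE
    for (try in 1:80) {
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      cand <- pos[t, ] + bond * dir
      prev <- pos[seq_len(max(1L, t - 1L)), , drop = FALSE]
      if (t < 2L || min(sqrt(rowSums(sweep(prev, 2, cand)^2))) >= min_sep) {
        ok <- TRUE; break
      }
    }
    if (!ok) cand <- pos[t, ] + bond * c(1, 0, 0)  # give up on avoidance
    pos[t + 1L, ] <- cand
  }
  pos
}

#' Parse a Calpha trace from PDB-format text
#'
#' Reads ATOM records (CA atoms) and, when present, SEQRES records of one
#' explicitly selected chain. Residues present in SEQRES but absent from
#' the coordinates are returned unresolved with no position. Coordinates
#' are converted from Angstrom to nm. Duplicate altloc CA atoms keep the
#' highest occupancy (with a warning).
#'
#' @param x Path to a PDB file, or a character vector of PDB lines.
#' @param chain Chain identifier; mandatory when the file holds more than
#'   one chain.
#' @return List of class `calpha_trace`: `sequence` (one-letter vector),
#'   `positions` (n x 3, nm, NA rows where unresolved), `resolved`
#'   (logical), `resseq` (author residue numbers), `chain`.
#' @export
parse_calpha_trace <- function(x, chain = NULL) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    readLines(x, warn = FALSE) else unlist(strsplit(x, "\n"))
  atom <- lines[startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")]
  atom <- atom[substr(atom, 13, 16) == " CA " | substr(atom, 13, 16) == "CA  "]
  atom <- atom[substr(atom, 18, 20) %in% names(.AA3TO1)]
  if (length(atom) == 0L) stop("format error: no protein CA atoms found")
  ch <- substr(atom, 22, 22)
  chains <- unique(ch)
  if (is.null(chain)) {
    if (length(chains) > 1L)
      stop("multiple chains present (", paste(chains, collapse = ", "),
           "); select one explicitly")
    chain <- chains
  }
  atom <- atom[ch == chain]
  if (length(atom) == 0L) stop("no CA atoms for chain '", chain, "'")

  resseq <- as.integer(substr(atom, 23, 26))
  icode <- substr(atom, 27, 27)
  key <- paste0(resseq, icode)
  occ <- suppressWarnings(as.numeric(substr(atom, 55, 60)))
  occ[is.na(occ)] <- 1
  if (anyDuplicated(key)) {
    warning("duplicate altloc CA records; keeping highest occupancy")
    keep <- !logical(length(key))
    for (k in unique(key[duplicated(key)])) {
      at <- which(key == k)
      keep[at] <- FALSE; keep[at[which.max(occ[at])]] <- TRUE
    }
    atom <- atom[keep]; resseq <- resseq[keep]; key <- key[keep]
  }
  res3 <- substr(atom, 18, 20)
  obs_seq <- unname(.AA3TO1[res3])
  xyz <- cbind(as.numeric(substr(atom, 31, 38)),
               as.numeric(substr(atom, 39, 46)),
               as.numeric(substr(atom, 47, 54))) / 10  # Angstrom -> nm

  seqres <- lines[startsWith(lines, "SEQRES") & substr(lines, 12, 12) == chain]
  if (length(seqres)) {
    toks <- unlist(strsplit(trimws(substr(seqres, 20, 70)), "\\s+"))
    toks <- toks[toks %in% names(.AA3TO1)]
    full_seq <- unname(.AA3TO1[toks])
    n <- length(full_seq)
    ## align observed residues to SEQRES via author numbering offset
    offset <- resseq[1] - 1L
    idx <- resseq - offset
    if (any(idx < 1L) || any(idx > n) ||
        !all(full_seq[idx] == obs_seq)) {
      ## fall back: first-observed residue may not be SEQRES position 1;
      ## scan for a consistent offset
      found <- FALSE
      for (off in (min(resseq) - 1L):(min(resseq) - 1L + n)) {
        idx <- resseq - off
        if (all(idx >= 1L) && all(idx <= n) &&
            all(full_seq[idx] == obs_seq)) { found <- TRUE; break }
      }
      if (!found) stop("cannot align ATOM residues to SEQRES for chain '",
                       chain, "'")
    }
    positions <- matrix(NA_real_, n, 3)
    positions[idx, ] <- xyz
    resolved <- logical(n); resolved[idx] <- TRUE
    resnum <- seq_len(n) + (resseq[1] - idx[1])
    out <- list(sequence = full_seq, positions = positions,
                resolved = resolved, resseq = resnum, chain = chain)
  } else {
    if (is.unsorted(resseq))
      stop("non-monotone residue numbering in chain '", chain, "'")
    out <- list(sequence = obs_seq, positions = xyz,
                resolved = rep(TRUE, length(obs_seq)), resseq = resseq,
                chain = chain)
  }
  class(out) <- "calpha_trace"
  out
}

#' Complete disordered regions of a Calpha trace
#'
#' Residues missing from the crystal coordinates are grown as disordered
#' beads by a seeded self-avoiding walk at backbone-bond spacing: interior
#' gaps are bridged between their resolved anchors, terminal stretches grow
#' freely from their anchor. Resolved beads are never moved. The elastic
#' network is then built over the structured beads only.
#'
#' @param trace A `calpha_trace` (or compatible list).
#' @param seed Seed for the stochastic placement.
#' @param chain_id Chain label of the resulting model.
#' @param backbone_r0 Backbone bond length, nm.
#' @param elastic_cutoff Elastic network cutoff, nm.
#' @return A `cg_model` whose `structured` mask marks the resolved beads.
#' @export
model_missing_regions <- function(trace, seed = 1L, chain_id = "KAP",
                                  backbone_r0 = 0.38, elastic_cutoff = 1.4) {
  seq <- trace$sequence
  n <- length(seq)
  resolved <- trace$resolved
  pos <- trace$positions
  if (!any(resolved)) stop("trace has no resolved residues")
  if (all(resolved))
    return(cg_model(seq, pos, structured = resolved, chain_id = chain_id,
                    backbone_r0 = backbone_r0,
                    elastic_cutoff = elastic_cutoff))
  ## feasibility of interior gaps: m missing beads bridge with m+1 segments
  runs <- rle(resolved)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (k in seq_along(runs$values)) {
    if (runs$values[k]) next
    a <- starts[k] - 1L; b <- ends[k] + 1L
    if (a >= 1L && b <= n) {
      d <- sqrt(sum((pos[b, ] - pos[a, ])^2))
      m <- runs$lengths[k]
      if (d > (m + 1L) * backbone_r0 * (1 + 1e-9))
        stop("unresolved stretch of ", m, " residues spans ",
             round(d, 2), " nm: not bridgeable at bond length ",
             backbone_r0, " nm")
    }
  }
  pos <- .with_seed(seed, {
    p <- pos
    for (k in seq_along(runs$values)) {
      if (runs$values[k]) next
      i0 <- starts[k]; i1 <- ends[k]
      a <- i0 - 1L; b <- i1 + 1L
      if (a >= 1L && b <= n) {
        p[i0:i1, ] <- .bridge_walk(p[a, ], p[b, ], i1 - i0 + 1L,
                                   backbone_r0, p[resolved, , drop = FALSE])
      } else if (a >= 1L) {           # C-terminal tail
        tail <- .self_avoiding_walk(i1 - i0 + 2L, backbone_r0,
                                    start = p[a, ])
        p[i0:i1, ] <- tail[-1, , drop = FALSE]
      } else {                        # N-terminal tail, grow backwards
        tail <- .self_avoiding_walk(i1 - i0 + 2L, backbone_r0,
                                    start = p[b, ])
        p[i0:i1, ] <- tail[rev(seq_len(i1 - i0 + 1L) + 1L), , drop = FALSE]
      }
    }
    p
  })
  cg_model(seq, pos, structured = resolved, chain_id = chain_id,
           backbone_r0 = backbone_r0, elastic_cutoff = elastic_cutoff)
}

## bridge m beads between anchors A and B with segments of length `bond`,
## keeping the walk feasible (remaining reach >= remaining distance)
.bridge_walk <- function(A, B, m, bond, avoid, min_sep = 0.34) {
  out <- matrix(0, m, 3)
  P <- A
  for (t in seq_len(m)) {
    rem <- (m - t) + 1L              # segments left after placing bead t
    placed <- FALSE
    for (try in 1:100) {
      dB <- B - P; dist <- sqrt(sum(dB^2))
      w <- runif(1)^2                # bias toward target, random otherwise
      dir <- w * (if (dist > 0) dB / dist else rnorm(3)) + (1 - w) * rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      cand <- P + bond * dir
      if (sqrt(sum((cand - B)^2)) > rem * bond) next
      if (nrow(avoid) &&
          min(sqrt(rowSums(sweep(avoid, 2, cand)^2))) < min_sep) next
      placed <- TRUE; break
    }
    if (!placed) {                   # deterministic fallback toward B
      dB <- B - P; dist <- sqrt(sum(dB^2))
      if (dist >= bond) cand <- P + bond * dB / dist
      else {
        perp <- c(dB[2], -dB[1], 0)
        if (sum(perp^2) < 1e-12) perp <- c(1, 0, 0)
        cand <- P + bond * perp / sqrt(sum(perp^2))
      }
    }
    out[t, ] <- cand
    P <- cand
  }
  out
}

#' @export
print.cg_model <- function(x, ...) {
  cat("cg_model '", x$chain_id, "': ", nchar(x$sequence), " beads, ",
      sum(x$structured), " structured, net charge ",
      sprintf("%+d", sum(x$charges)), " (NCPR ",
      sprintf("%.3f", compute_ncpr(x)), "), ",
      nrow(x$elastic), " elastic pairs\n", sep = "")
  invisible(x)
}

## ---- serialization -------------------------------------------------------

#' Write / read a cg_model as JSON text
#'
#' Numbers are written at 17 significant digits so that a write/read
#' round-trip reproduces every field bit-for-bit.
#'
#' @param model A `cg_model`.
#' @param path File path.
#' @return `read_cg_model` returns the `cg_model`; `write_cg_model` the
#'   path, invisibly.
#' @export
write_cg_model <- function(model, path) {
  validate_cg_model(model)
  vec <- function(x) paste0("[", paste(x, collapse = ","), "]")
  pos <- apply(model$positions, 1, function(p)
    paste0("[", paste(.num17(p), collapse = ","), "]"))
  json <- paste0(
    '{"format":"kapcg-model","version":1,',
    '"chain_id":', jsonlite::toJSON(model$chain_id, auto_unbox = TRUE), ',',
    '"sequence":"', model$sequence, '",',
    '"backbone_r0":', .num17(model$backbone_r0), ',',
    '"positions":[', paste(pos, collapse = ","), '],',
    '"charges":', vec(model$charges), ',',
    '"aromatic":', vec(as.integer(model$aromatic)), ',',
    '"structured":', vec(as.integer(model$structured)), ',',
    '"elastic_i":', vec(model$elastic$i), ',',
    '"elastic_j":', vec(model$elastic$j), ',',
    '"elastic_r0":', vec(.num17(model$elastic$r0)), '}')
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_cg_model
#' @export
read_cg_model <- function(path) {
  d <- jsonlite::fromJSON(readLines(path, warn = FALSE))
  if (is.null(d$format) || d$format != "kapcg-model")
    stop("not a kapcg model file: ", path)
  pos <- matrix(as.numeric(d$positions), ncol = 3, byrow = FALSE)
  if (is.matrix(d$positions)) pos <- d$positions
  structure(list(
    sequence = d$sequence,
    positions = unname(pos),
    charges = as.integer(d$charges),
    aromatic = as.logical(d$aromatic),
    structured = as.logical(d$structured),
    backbone_r0 = d$backbone_r0,
    elastic = data.frame(i = as.integer(d$elastic_i),
                         j = as.integer(d$elastic_j),
                         r0 = as.numeric(d$elastic_r0)),
    chain_id = d$chain_id
  ), class = "cg_model")
}

## ---- annotations ---------------------------------------------------------

#' Region annotation of a HEAT-repeat receptor
#'
#' Labeled residue spans (1-based, inclusive) classifying each receptor
#' residue as A-helix, B-helix or linker of a given HEAT repeat. By the
#' solenoid convention used throughout the package, B-helices form the
#' inner concave surface and A-helices the outer convex surface.
#'
#' @param start,end Integer vectors of span bounds (inclusive).
#' @param heat_index HEAT repeat number per span.
#' @param label One of `"A"`, `"B"`, `"linker"` per span.
#' @return Data frame of class `region_annotation`.
#' @export
region_annotation <- function(start, end, heat_index, label) {
  if (!all(label %in% c("A", "B", "linker")))
    stop("labels must be A, B or linker")
  if (any(end < start)) stop("span end before start")
  ann <- data.frame(start = as.integer(start), end = as.integer(end),
                    heat_index = as.integer(heat_index),
                    label = as.character(label))
  ann <- ann[order(ann$start), ]
  if (nrow(ann) > 1L && any(ann$start[-1] <= ann$end[-nrow(ann)]))
    stop("overlapping spans")
  rownames(ann) <- NULL
  class(ann) <- c("region_annotation", "data.frame")
  ann
}

#' @rdname region_annotation
#' @param path TSV file with columns start, end, heat_index, label.
#' @export
read_region_annotation <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  region_annotation(d$start, d$end, d$heat_index, d$label)
}

#' @rdname region_annotation
#' @param ann A `region_annotation`.
#' @export
write_region_annotation <- function(ann, path) {
  write.table(as.data.frame(ann), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Native binding-site sets of a receptor
#'
#' Residue-index lists (1-based) per binding-partner class. A class with
#' no known sites is stored as an empty set and reported as absent
#' downstream (the "(-)" convention).
#'
#' @param cargo,ibb,rangtp,fg_nup Integer vectors of residue indices.
#' @param n_residues Receptor length for validation (optional).
#' @return List of class `binding_site_set`.
#' @export
binding_site_set <- function(cargo = integer(0), ibb = integer(0),
                             rangtp = integer(0), fg_nup = integer(0),
                             n_residues = NULL) {
  sets <- list(cargo = sort(unique(as.integer(cargo))),
               ibb = sort(unique(as.integer(ibb))),
               rangtp = sort(unique(as.integer(rangtp))),
               fg_nup = sort(unique(as.integer(fg_nup))))
  if (!is.null(n_residues)) {
    all_idx <- unlist(sets)
    if (length(all_idx) && (any(all_idx < 1L) || any(all_idx > n_residues)))
      stop("binding-site index outside 1..", n_residues)
  }
  structure(sets, class = "binding_site_set")
}

#' @rdname binding_site_set
#' @param path TSV file with columns class, residue_index.
#' @export
read_binding_sites <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  get <- function(cl) d$residue_index[d$class == cl]
  binding_site_set(get("cargo"), get("ibb"), get("rangtp"), get("fg_nup"))
}

#' @rdname binding_site_set
#' @param sites A `binding_site_set`.
#' @export
write_binding_sites <- function(sites, path) {
  d <- do.call(rbind, lapply(names(sites), function(cl)
    if (length(sites[[cl]])) data.frame(class = cl,
                                        residue_index = sites[[cl]])))
  if (is.null(d)) d <- data.frame(class = character(0),
                                  residue_index = integer(0))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
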