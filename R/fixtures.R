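# Synthetic structure generators ---------------------------------------------
#
# Seeded generators of toy C-alpha structures, families and conformational
# pairs so every analysis is testable without downloading real structures.
# All fixtures are poly-alanine; seeded generation is reproducible.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

random_unit <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

rotation_about <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

helix_coords <- function(n, rise = 0.15, radius = 0.23, twist = 100) {
  i <- seq_len(n) - 1
  th <- i * twist * pi / 180
  cbind(radius * cos(th), radius * sin(th), i * rise)
}

# confined self-avoiding walk: 0.38 nm steps, hard core 0.30 nm, kept inside
# a ball sized for roughly protein-like density
blob_coords <- function(n, step = 0.38, hard_core = 0.30,
                        max_tries = 300, max_restarts = 60) {
  rmax <- 0.3 * n^(1 / 3) + 0.45
  for (restart in seq_len(max_restarts)) {
    pts <- matrix(0, n, 3)
    ok <- TRUE
    for (k in 2:n) {
      placed <- FALSE
      for (t in seq_len(max_tries)) {
        cand <- pts[k - 1, ] + step * random_unit()
        if (sqrt(sum(cand^2)) > rmax) next
        d2 <- rowSums(sweep(pts[seq_len(k - 1), , drop = FALSE], 2, cand)^2)
        if (min(d2) >= hard_core^2) { pts[k, ] <- cand; placed <- TRUE; break }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(sweep(pts, 2, colMeans(pts)))
  }
  flexcmp_error("failed to grow a self-avoiding blob within retry bounds",
                "flexcmp_parse_error")
}

dumbbell_coords <- function(n_domain = 12, n_linker = 4) {
  b1 <- blob_coords(n_domain)
  b2 <- blob_coords(n_domain)
  # extended helical linker chained onto domain 1's outermost bead; a
  # perfectly straight (or planar) linker would bend or twist for free
  # (soft collinear degeneracy) and make a useless hinge fixture
  amp <- 0.12
  dx <- sqrt(0.38^2 - 2 * amp^2 * (1 - cos(100 * pi / 180)))
  offset <- function(k) amp * c(0, cos(k * 100 * pi / 180),
                                sin(k * 100 * pi / 180))
  start <- b1[which.max(b1[, 1]), ]
  linker <- t(vapply(seq_len(n_linker), function(k)
    start + c(k * dx, 0, 0) + offset(k), numeric(3)))
  # continue the chain into domain 2's innermost bead
  target <- start + c((n_linker + 1) * dx, 0, 0) + offset(n_linker + 1)
  b2 <- sweep(b2, 2, target - b2[which.min(b2[, 1]), ], "+")
  rbind(b1, linker, b2)
}

#' Generate a synthetic C-alpha structure
#'
#' `helix`: ideal helix (rise 0.15 nm, radius 0.23 nm, 100 degrees per
#' residue, giving ~0.38 nm consecutive C-alpha spacing). `compact_blob`:
#' confined self-avoiding random walk with 0.38 nm steps and a 0.30 nm hard
#' core. `two_domain_dumbbell`: two compact blobs joined by an extended
#' 4-residue linker (a hinge fixture; `n_residues` is ignored in favour of
#' `n_domain`/`n_linker`). All fixtures are poly-alanine and satisfy the
#' minimum-distance validation by construction.
#'
#' @param kind one of `"helix"`, `"compact_blob"`, `"two_domain_dumbbell"`.
#' @param n_residues bead count (helix and blob).
#' @param seed integer seed; generation is reproducible.
#' @param n_domain,n_linker dumbbell geometry.
#' @param path optional file path; when given the structure is also written
#'   as a PDB file.
#' @param structure_id label; defaults to `kind`.
#' @return a `calpha_structure`.
#' @export
make_structure <- function(kind = c("helix", "compact_blob", "two_domain_dumbbell"),
                           n_residues = 20, seed = 1, n_domain = 12,
                           n_linker = 4, path = NULL, structure_id = NULL) {
  kind <- match.arg(kind)
  if (n_residues < 5) flexcmp_error("need at least 5 residues", "flexcmp_parse_error")
  xyz <- with_seed(seed, switch(kind,
    helix = helix_coords(n_residues),
    compact_blob = blob_coords(n_residues),
    two_domain_dumbbell = dumbbell_coords(n_domain, n_linker)))
  s <- calpha_structure(xyz, structure_id = if (is.null(structure_id)) kind
                        else structure_id)
  validate_min_distance(s)
  if (!is.null(path)) write_pdb_calpha(s, path)
  s
}

perturb_structure <- function(s, sigma, max_tries = 200) {
  for (t in seq_len(max_tries)) {
    cand <- s$coordinates + matrix(stats::rnorm(length(s$coordinates), sd = sigma),
                                   ncol = 3)
    s2 <- calpha_structure(cand, structure_id = s$structure_id,
                           residue_labels = s$residue_labels)
    ok <- tryCatch({ validate_min_distance(s2); TRUE },
                   flexcmp_validation_error = function(e) FALSE)
    if (ok) return(s2)
  }
  flexcmp_error("could not generate a clash-free perturbed copy",
                "flexcmp_parse_error")
}

#' Generate synthetic structural families with a consistent alignment
#'
#' Each family has one base fold (a compact blob); copies are the base fold
#' with seeded Gaussian coordinate noise, re-validated against the minimum
#' distance rule. With `indels = TRUE`, some copies lose a short internal
#' segment and the alignment gains the corresponding gap columns; the
#' written alignment is always consistent with the structures.
#'
#' @param n_families number of families.
#' @param n_copies copies per family.
#' @param n_residues residues in each base fold.
#' @param noise_sigma coordinate noise (nm) applied to each copy.
#' @param seed integer seed.
#' @param indels introduce short deletions in some copies.
#' @param dir optional output directory; when given, PDB files and the
#'   gapped FASTA are written there.
#' @return list with `structures` (list of `calpha_structure`), `alignment`
#'   (a `gapped_alignment`), `family` (integer vector of family labels).
#' @export
make_family <- function(n_families = 2, n_copies = 5, n_residues = 30,
                        noise_sigma = 0.02, seed = 1, indels = FALSE,
                        dir = NULL) {
  if (n_copies < 2 && n_families < 2)
    flexcmp_error("need at least 2 structures overall", "flexcmp_parse_error")
  res <- with_seed(seed, {
    structures <- list()
    seqs <- character()
    family <- integer()
    names_ <- character()
    for (f in seq_len(n_families)) {
      base <- calpha_structure(blob_coords(n_residues),
                               structure_id = sprintf("fam%d_base", f))
      for (c in seq_len(n_copies)) {
        id <- sprintf("fam%d_copy%d", f, c)
        s <- perturb_structure(base, noise_sigma)
        gaps <- integer()
        if (indels && c > 1 && stats::runif(1) < 0.5) {
          start <- sample.int(n_residues - 6, 1) + 2
          gaps <- start:(start + sample(2:3, 1) - 1)
          s <- calpha_structure(s$coordinates[-gaps, , drop = FALSE],
                                structure_id = id)
          s <- tryCatch({ validate_min_distance(s); s },
                        flexcmp_validation_error = function(e) NULL)
          if (is.null(s)) { # deletion caused a clash; keep the full copy
            gaps <- integer()
            s <- perturb_structure(base, noise_sigma)
          }
        }
        s$structure_id <- id
        chars <- rep("A", n_residues)
        chars[gaps] <- "-"
        structures <- c(structures, list(s))
        seqs <- c(seqs, paste(chars, collapse = ""))
        family <- c(family, f)
        names_ <- c(names_, id)
      }
    }
    list(structures = structures,
         alignment = gapped_alignment(seqs, names_),
         family = family)
  })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (s in res$structures)
      write_pdb_calpha(s, file.path(dir, paste0(s$structure_id, ".pdb")))
    fasta <- file.path(dir, "alignment.fasta")
    writeLines(as.vector(rbind(paste0(">", res$alignment$names),
                               res$alignment$seqs)), fasta)
  }
  res
}

#' Generate an open/closed conformational pair
#'
#' Starts from a two-domain dumbbell ("open") and produces a "closed" copy
#' by rotating the second domain about a hinge axis through the middle of
#' the linker. The two conformers share sequence and residue count, so they
#' feed directly into [overlap_analysis()]. A rotation angle of zero yields
#' identical conformers (which overlap analysis rejects as degenerate).
#'
#' @param n_domain residues per domain.
#' @param n_linker residues in the linker.
#' @param angle_deg hinge rotation angle in degrees (default 30).
#' @param seed integer seed.
#' @param max_tries resampling attempts when the rotation causes a clash.
#' @return list with `open` and `closed` (`calpha_structure` objects).
#' @export
make_open_closed_pair <- function(n_domain = 12, n_linker = 4, angle_deg = 30,
                                  seed = 1, max_tries = 100) {
  open_s <- make_structure("two_domain_dumbbell", seed = seed,
                           n_domain = n_domain, n_linker = n_linker,
                           structure_id = "open")
  closed <- with_seed(seed + 1, {
    n <- nrow(open_s$coordinates)
    hinge_idx <- n_domain + ceiling(n_linker / 2)
    hinge <- open_s$coordinates[hinge_idx, ]
    moving <- (hinge_idx + 1):n
    out <- NULL
    for (t in seq_len(max_tries)) {
      axis <- random_unit()
      axis <- axis - c(1, 0, 0) * sum(axis * c(1, 0, 0))  # perpendicular to linker
      if (sqrt(sum(axis^2)) < 1e-3) next
      R <- rotation_about(axis, angle_deg * pi / 180)
      xyz <- open_s$coordinates
      xyz[moving, ] <- sweep(sweep(xyz[moving, , drop = FALSE], 2, hinge) %*% t(R),
                             2, hinge, "+")
      cand <- calpha_structure(xyz, structure_id = "closed")
      ok <- tryCatch({ validate_min_distance(cand); TRUE },
                     flexcmp_validation_error = function(e) FALSE)
      if (ok) { out <- cand; break }
    }
    out
  })
  if (is.null(closed))
    flexcmp_error("could not produce a clash-free closed conformer",
                  "flexcmp_parse_error")
  list(open = open_s, closed = closed)
}
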