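two_structs <- function(n = 10, seeds = c(1, 2), noise = 0) {
  lapply(seq_along(seeds), function(k) {
    s <- make_structure("compact_blob", n_residues = n, seed = seeds[k])
    s$structure_id <- paste0("s", k)
    s
  })
}

identity_aln <- function(structures) {
  gapped_alignment(vapply(structures, function(s) s$one_letter_sequence,
                          character(1)),
                   vapply(structures, function(s) s$structure_id, character(1)))
}

test_that("alignment mapping finds conserved columns and reports mismatches", {
  s1 <- calpha_structure(helix_like <- make_structure("helix", n_residues = 4 + 1,
                                                      seed = 1)$coordinates[1:4, ],
                         residue_labels = data.frame(
                           chain = "A", resno = 1:4, insert = "",
                           resname = c("ALA", "CYS", "ASP", "GLU")))
  s2 <- calpha_structure(s1$coordinates[-3, , drop = FALSE],
                         residue_labels = data.frame(
                           chain = "A", resno = 1:3, insert = "",
                           resname = c("ALA", "CYS", "GLU")))
  aln <- gapped_alignment(c("ACDE", "AC-E"), c("s1", "s2"))
  map <- map_alignment(aln, list(s1, s2))
  expect_equal(map$conserved_columns, c(1, 2, 4))
  expect_equal(map$nonconserved, 3)
  expect_equal(map$column_to_residue[[2]], c(1L, 2L, NA, 3L))

  bad <- gapped_alignment(c("ACDE", "AC-D"), c("s1", "s2"))
  err <- expect_error(map_alignment(bad, list(s1, s2)),
                      class = "flexcmp_mapping_error")
  expect_match(conditionMessage(err), "residue 3")

  # three identical ungapped records: every column conserved
  trio <- two_structs(8, c(3, 3, 3))
  map3 <- map_alignment(identity_aln(trio), trio)
  expect_equal(map3$conserved_columns, 1:8)
})

test_that("the identity reduction returns the full Hessian", {
  ss <- two_structs(8, c(4, 5))
  aln <- identity_aln(ss)
  map <- map_alignment(aln, ss)
  h <- build_hessian(ss[[1]])
  red <- effective_hessian(h, map, 1)
  expect_equal(red$effective_hessian, h$matrix, tolerance = 1e-12)
  expect_equal(red$modes$n_trivial, 6)
})

test_that("the Schur complement matches numerically minimised full energy", {
  set.seed(100)
  n_checked <- 0
  for (trial in 1:6) {
    n <- sample(10:16, 1)
    s <- make_structure("compact_blob", n_residues = n, seed = 200 + trial)
    h <- build_hessian(s)
    a_res <- sort(sample(n, sample(5:(n - 2), 1)))
    b_res <- setdiff(seq_len(n), a_res)
    ai <- as.vector(vapply(a_res, function(r) (3 * r - 3) + 1:3, numeric(3)))
    bi <- as.vector(vapply(b_res, function(r) (3 * r - 3) + 1:3, numeric(3)))
    # reuse the mapping machinery with a synthetic gap pattern
    chars <- rep("A", n); chars[b_res] <- "-"
    aln <- gapped_alignment(c(paste(rep("A", n), collapse = ""),
                              paste(chars, collapse = "")), c("full", "sub"))
    ssub <- calpha_structure(s$coordinates[a_res, , drop = FALSE])
    map <- map_alignment(aln, list(s, ssub))
    red <- effective_hessian(h, map, 1)
    H <- h$matrix
    for (rep in 1:4) {
      xa <- rnorm(length(ai), sd = 0.05)
      direct <- 0.5 * as.numeric(t(xa) %*% red$effective_hessian %*% xa)
      efun <- function(xb) {
        x <- numeric(3 * n); x[ai] <- xa; x[bi] <- xb
        0.5 * as.numeric(t(x) %*% H %*% x)
      }
      egrad <- function(xb) {
        x <- numeric(3 * n); x[ai] <- xa; x[bi] <- xb
        as.numeric(H %*% x)[bi]
      }
      opt <- stats::optim(numeric(length(bi)), efun, egrad, method = "BFGS",
                          control = list(maxit = 2000, reltol = 1e-15))
      expect_equal(direct, opt$value, tolerance = 1e-8)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 20)
})

test_that("rigidly extended rigid motions have zero energy under the reduction", {
  ss <- two_structs(12, c(7, 8))
  chars <- rep("A", 12); chars[c(3, 9)] <- "-"
  aln <- gapped_alignment(c(paste(rep("A", 12), collapse = ""),
                            paste(chars, collapse = "")), c("s1", "s2"))
  ssub <- calpha_structure(ss[[1]]$coordinates[-c(3, 9), , drop = FALSE])
  map <- map_alignment(aln, list(ss[[1]], ssub))
  h <- build_hessian(ss[[1]])
  red <- effective_hessian(h, map, 1)
  a_res <- red$conserved_residues
  B <- rigid_basis(ss[[1]]$coordinates[a_res, , drop = FALSE])
  Hr <- red$effective_hessian
  for (k in seq_len(ncol(B))) {
    v <- B[, k] / sqrt(sum(B[, k]^2))
    expect_lt(abs(t(v) %*% Hr %*% v), 1e-9 * max(abs(Hr)))
  }
  expect_equal(red$modes$n_trivial, 6)
})

test_that("aligned profiles match single-structure profiles and blank the gaps", {
  base <- make_structure("compact_blob", n_residues = 14, seed = 33)
  s1 <- base; s1$structure_id <- "s1"
  s2 <- calpha_structure(base$coordinates[-c(6, 7), , drop = FALSE],
                         structure_id = "s2")
  aln <- gapped_alignment(c(paste(rep("A", 14), collapse = ""),
                            paste(replace(rep("A", 14), 6:7, "-"), collapse = "")),
                          c("s1", "s2"))
  structures <- list(s1, s2)
  map <- map_alignment(aln, structures)
  mode_sets <- lapply(structures, function(s) compute_modes(build_hessian(s)))
  prof <- aligned_profiles(structures, map, mode_sets)
  tf <- prof$fluctuations$table
  expect_true(all(is.na(tf$s2[6:7])))
  expect_false(anyNA(tf$s1))
  expect_equal(tf$s1, fluctuations(mode_sets[[1]])$values, tolerance = 1e-12)
  expect_equal(tf$s2[-c(6, 7)], fluctuations(mode_sets[[2]])$values,
               tolerance = 1e-12)
  td <- prof$deformation$table
  expect_equal(td$s1, deformation_energies(mode_sets[[1]], s1)$values,
               tolerance = 1e-12)
  expect_true(all(is.na(td$s2[6:7])))

  # two identical structures under an identity alignment: identical columns
  twins <- two_structs(10, c(9, 9))
  mtw <- map_alignment(identity_aln(twins), twins)
  ptw <- aligned_profiles(twins, mtw,
                          lapply(twins, function(s) compute_modes(build_hessian(s))))
  expect_equal(ptw$fluctuations$table$s1, ptw$fluctuations$table$s2,
               tolerance = 1e-12)
})

test_that("RMSIP: self-similarity, orthogonal subspaces, brute-force oracle", {
  ss <- two_structs(10, c(11, 12))
  map <- map_alignment(identity_aln(ss), ss)
  red <- lapply(1:2, function(k) effective_hessian(build_hessian(ss[[k]]), map, k))
  expect_equal(rmsip(red[[1]], red[[1]]), 1, tolerance = 1e-10)
  r12 <- rmsip(red[[1]], red[[2]])
  expect_true(r12 >= 0 && r12 <= 1)
  expect_equal(r12, oracle_rmsip(red[[1]], red[[2]]), tolerance = 1e-12)

  # constructed orthogonal subspaces
  D <- red[[1]]$modes$displacements
  fakeA <- synthetic_reduced(seq_len(10), D[, 1:10])
  fakeB <- synthetic_reduced(seq_len(10), D[, 11:20])
  expect_equal(rmsip(fakeA, fakeB), 0, tolerance = 1e-10)
  expect_warning(
    rmsip(synthetic_reduced(1:5, D[, 1:5]), synthetic_reduced(1:5, D[, 1:5])),
    "available")
})

test_that("BC: self-similarity, symmetry, bounds and brute-force oracle", {
  set.seed(9)
  for (trial in 1:4) {
    ss <- two_structs(9, c(20 + trial, 40 + trial))
    map <- map_alignment(identity_aln(ss), ss)
    red <- lapply(1:2, function(k)
      effective_hessian(build_hessian(ss[[k]]), map, k))
    expect_equal(bhattacharyya(red[[1]], red[[1]]), 1, tolerance = 1e-9)
    b12 <- bhattacharyya(red[[1]], red[[2]])
    b21 <- bhattacharyya(red[[2]], red[[1]])
    expect_equal(b12, b21, tolerance = 1e-10)
    expect_true(b12 > 0 && b12 <= 1 + 1e-9)
    expect_equal(b12, oracle_bc(red[[1]], red[[2]]), tolerance = 1e-8)
  }
  # the two rank-reduction counts are reported and sensible
  ss <- two_structs(9, c(61, 62))
  map <- map_alignment(identity_aln(ss), ss)
  red <- lapply(1:2, function(k) effective_hessian(build_hessian(ss[[k]]), map, k))
  det_ <- bhattacharyya(red[[1]], red[[2]], details = TRUE)
  expect_true(det_$n >= 1 && det_$n <= length(red[[1]]$modes$eigenvalues))
  expect_true(det_$s >= 1)
})

test_that("RMSIP and BC are invariant under rigid motion of either input", {
  ss <- two_structs(10, c(3, 14))
  map <- map_alignment(identity_aln(ss), ss)
  red <- lapply(1:2, function(k) effective_hessian(build_hessian(ss[[k]]), map, k))
  r0 <- rmsip(red[[1]], red[[2]])
  b0 <- bhattacharyya(red[[1]], red[[2]])
  set.seed(5)
  s2r <- transform_structure(ss[[2]])
  s2r$structure_id <- "s2"
  red2 <- effective_hessian(build_hessian(s2r), map, 2)
  expect_equal(rmsip(red[[1]], red2), r0, tolerance = 1e-8)
  expect_equal(bhattacharyya(red[[1]], red2), b0, tolerance = 1e-8)
})

test_that("mean BC to noisy copies degrades monotonically with noise", {
  sigmas <- c(0.01, 0.05, 0.1)
  base <- make_structure("compact_blob", n_residues = 12, seed = 50)
  base$structure_id <- "s1"
  means <- vapply(sigmas, function(sig) {
    vals <- vapply(1:10, function(seed) {
      set.seed(1000 + seed)
      copy <- flexcmp:::perturb_structure(base, sig)
      copy$structure_id <- "s2"
      ss <- list(base, copy)
      map <- map_alignment(identity_aln(ss), ss)
      red <- lapply(1:2, function(k)
        effective_hessian(build_hessian(ss[[k]]), map, k))
      bhattacharyya(red[[1]], red[[2]])
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("similarity matrices are symmetric with unit diagonal and cluster", {
  ss <- two_structs(10, c(9, 9, 9))  # identical trio
  map <- map_alignment(identity_aln(ss), ss)
  red <- lapply(seq_along(ss), function(k)
    effective_hessian(build_hessian(ss[[k]]), map, k))
  sm <- similarity_matrix(red, "BC")
  expect_equal(sm$values, matrix(1, 3, 3, dimnames = dimnames(sm$values)),
               tolerance = 1e-9)
  expect_lt(max(sm$dendrogram$height), 1e-9)
  expect_identical(sm$values, t(sm$values))

  fam <- make_family(seed = 4)
  mapf <- map_alignment(fam$alignment, fam$structures)
  redf <- lapply(seq_along(fam$structures), function(k)
    effective_hessian(build_hessian(fam$structures[[k]]), mapf, k))
  smf <- similarity_matrix(redf, "BC")
  expect_identical(smf$values, t(smf$values))
  cl <- stats::cutree(smf$dendrogram, 2)
  expect_equal(length(unique(cl[fam$family == 1])), 1)
  expect_equal(length(unique(cl[fam$family == 2])), 1)
  expect_false(cl[1] == cl[10])
})

test_that("BC separates spectra that RMSIP cannot distinguish", {
  # constructed case: the two families span the same ten lowest-mode
  # subspace (so RMSIP is blind to the difference by construction) but
  # distribute the eigenvalues over those directions in opposite order;
  # only the covariance-based BC, which weighs directions by energy,
  # separates them.
  set.seed(123)
  dim3n <- 30
  Q <- qr.Q(qr(matrix(rnorm(dim3n^2), dim3n)))
  jitter_ev <- function(base) base * exp(rnorm(length(base), sd = 0.02))
  lam <- c(seq(1, 10), seq(50, 69))
  fams <- c(rep(1, 3), rep(2, 3))
  reds <- lapply(fams, function(f)
    synthetic_reduced(jitter_ev(lam),
                      if (f == 1) Q else Q[, c(10:1, 11:30)]))
  margin <- function(vals) {
    w <- b <- c()
    for (i in 1:5) for (j in (i + 1):6) {
      v <- vals[i, j]
      if (fams[i] == fams[j]) w <- c(w, v) else b <- c(b, v)
    }
    mean(w) - mean(b)
  }
  bc_m <- margin(similarity_matrix(reds, "BC")$values)
  rm_m <- margin(similarity_matrix(reds, "RMSIP")$values)
  expect_gt(bc_m, rm_m)
  expect_gt(bc_m, 0.05)
  expect_lt(abs(rm_m), 0.02)
})
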