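# Component scorers, their additivity, and the combined E_patch.

# minimal structure stub with chosen types/ASA for the lookup terms
score_stub <- function(types, asa) {
  n <- length(types)
  structure(list(
    residues = data.frame(
      res_id = paste0("A:", seq_len(n), ":"), chain = "A",
      resno = seq_len(n), icode = "", res_type = types, asa = asa,
      stringsAsFactors = FALSE)
  ), class = "spr_structure")
}

patch_of <- function(idx) {
  members <- if (length(idx)) paste0("A:", idx, ":") else character()
  ppiprop:::new_patch(members)
}

test_that("E_res applies ASA * QIPI / REF per member", {
  s <- score_stub(c("M", "G"), c(100, 50))
  expect_equal(score_eres(patch_of(1), s), 100 * 1.451 / 33.5)
  expect_equal(score_eres(patch_of(1:2), s),
               100 * 1.451 / 33.5 + 50 * 0.823 / 24.5)
  expect_equal(score_eres(patch_of(integer()), s), 0)   # empty sum
  s0 <- score_stub(c("M", "M"), c(0, 0))
  expect_equal(score_eres(patch_of(1:2), s0), 0)        # all-zero ASA
})

test_that("E_hydro is a plain table-lookup sum", {
  tables <- spr_constants()
  s <- score_stub(rep("W", 5), rep(10, 5))
  expect_equal(score_ehydro(patch_of(1:5), s), 5 * tables$hydro[["W"]])
  set.seed(77)
  types <- sample(ppiprop:::AA20, 12, replace = TRUE)
  s2 <- score_stub(types, rep(10, 12))
  manual <- 0
  for (t in types[c(2, 5, 9)]) manual <- manual + tables$hydro[[t]]
  expect_equal(score_ehydro(patch_of(c(2, 5, 9)), s2), manual)
  expect_equal(score_ehydro(patch_of(integer()), s2), 0)
})

test_that("E_cons sums PSSM self-scores minus the BLOSUM62 diagonal", {
  case <- toy_unbound_case(fixture_spec(seed = 51, n_per_side = 12),
                           conservation_offset = 0)
  surf <- surface_residues(case$struct)
  p <- ppiprop:::new_patch(surf[1:5])
  # offsets all zero: C_ir == B_rr everywhere
  expect_equal(score_econs(p, case$struct, case$pssm), 0)

  res <- case$struct$residues
  offsets <- rep(0, nrow(res))
  offsets[match(surf[2], res$res_id)] <- 3
  tf <- withr::local_tempfile(fileext = ".pssm")
  writeLines(make_toy_pssm(res$res_type, offsets), tf)
  pssm <- read_pssm(tf)
  expect_equal(score_econs(ppiprop:::new_patch(surf[2]), case$struct, pssm), 3)

  # brute-force per-position oracle on random offsets
  set.seed(88)
  offsets <- sample(-2:4, nrow(res), replace = TRUE)
  writeLines(make_toy_pssm(res$res_type, offsets), tf)
  pssm2 <- read_pssm(tf)
  members <- surf[c(1, 3, 5, 7)]
  manual <- sum(offsets[match(members, res$res_id)])
  expect_equal(score_econs(ppiprop:::new_patch(members), case$struct, pssm2),
               manual)
  expect_error(score_econs(p, case$struct, NULL), "configuration error")
})

test_that("the probe-sphere volume fraction matches geometry and an MC oracle", {
  # wall of atoms whose accessible spheres reach z = 0: a probe sphere
  # centred on the boundary is bisected
  g <- expand.grid(x = seq(-6, 6, by = 0.8), y = seq(-6, 6, by = 0.8))
  wall <- cbind(g$x, g$y, rep(-3.27, nrow(g)))
  radii <- rep(3.27, nrow(g))
  half <- sphere_outside_fraction(c(0, 0, 0), wall, radii)
  expect_equal(half, 0.5, tolerance = 0.05)
  expect_equal(half / (1 - half), 1, tolerance = 0.12)  # the E_sol term

  # deep inside the wall: fully occluded
  expect_equal(sphere_outside_fraction(c(0, 0, -3), wall, radii), 0)
  # far above: fully exposed
  expect_equal(sphere_outside_fraction(c(0, 0, 9), wall, radii), 1)

  # random convex occluder sets vs Monte-Carlo volume oracle
  set.seed(99)
  for (k in 1:3) {
    centers <- matrix(stats::rnorm(9, sd = 2), ncol = 3)
    radii_k <- stats::runif(3, 2, 3.5)
    ctr <- stats::rnorm(3, sd = 2)
    grid_est <- sphere_outside_fraction(ctr, centers, radii_k)
    mc <- mc_outside_fraction(ctr, centers, radii_k, 1.2, n = 1e6, seed = k)
    expect_equal(grid_est, mc, tolerance = 0.05)
  }
})

test_that("E_sol vanishes for buried members and is additive over members", {
  case <- toy_unbound_case(fixture_spec(seed = 52, n_per_side = 12))
  surf <- surface_residues(case$struct)
  p1 <- ppiprop:::new_patch(surf[1:3])
  p2 <- ppiprop:::new_patch(surf[4:6])
  both <- ppiprop:::new_patch(surf[1:6])
  e1 <- score_esol(p1, case$struct)
  e2 <- score_esol(p2, case$struct)
  expect_equal(score_esol(both, case$struct), e1 + e2, tolerance = 1e-9)
  expect_equal(score_esol(patch_of(integer()), case$struct), 0)

  # a residue with no solvent-exposed atoms contributes nothing
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
    c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
    c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1)
  )
  v <- 2 * v / sqrt(rowSums(v^2))
  caged <- compute_asa(make_structure(data.frame(
    chain = "A", resno = c(1, rep(2, 12)),
    elety = c("CA", paste0("C", 1:12)), element = "C",
    x = c(0, v[, 1]), y = c(0, v[, 2]), z = c(0, v[, 3])
  )))
  expect_equal(score_esol(ppiprop:::new_patch("A:1:"), caged), 0)
})

test_that("component scores are additive over disjoint member sets", {
  case <- toy_unbound_case(fixture_spec(seed = 53, n_per_side = 15))
  surf <- surface_residues(case$struct)
  half <- length(surf) %/% 2
  pa <- ppiprop:::new_patch(surf[1:half])
  pb <- ppiprop:::new_patch(surf[(half + 1):length(surf)])
  pu <- ppiprop:::new_patch(surf)
  for (fn in list(score_eres, score_ehydro)) {
    expect_equal(fn(pu, case$struct), fn(pa, case$struct) +
                   fn(pb, case$struct), tolerance = 1e-9)
  }
  expect_equal(score_econs(pu, case$struct, case$pssm),
               score_econs(pa, case$struct, case$pssm) +
                 score_econs(pb, case$struct, case$pssm))
})

test_that("E_patch combines the stored components with the weights", {
  case <- toy_unbound_case(fixture_spec(seed = 54, n_per_side = 12))
  surf <- surface_residues(case$struct)
  p <- ppiprop:::new_patch(surf[1:6])
  s0 <- score_patch(p, case$struct, weights = c(w1 = 0, w2 = 0, w3 = 0),
                    pssm = case$pssm)
  expect_equal(s0$e_patch, s0$e_res)
  s1 <- score_patch(p, case$struct, weights = c(w1 = 1, w2 = 0, w3 = 0),
                    pssm = case$pssm)
  expect_equal(s1$e_patch, s1$e_res + s1$e_hydro)
  sw <- score_patch(p, case$struct, weights = c(w1 = .5, w2 = .25, w3 = 2),
                    pssm = case$pssm)
  # recompute oracle: stored breakdown equals the component scorers
  expect_equal(sw$e_res, score_eres(p, case$struct))
  expect_equal(sw$e_hydro, score_ehydro(p, case$struct))
  expect_equal(sw$e_cons, score_econs(p, case$struct, case$pssm))
  expect_equal(sw$e_sol, score_esol(p, case$struct))
  expect_equal(sw$e_patch,
               sw$e_res + 0.5 * sw$e_hydro + 0.25 * sw$e_cons + 2 * sw$e_sol)
  expect_warning(score_patch(p, case$struct,
                             weights = c(w1 = 0, w2 = 1, w3 = 0)),
                 "no PSSM")
})

test_that("prediction is deterministic and confined to the surface", {
  case <- toy_unbound_case(fixture_spec(seed = 55, n_per_side = 15))
  t1 <- predict_interface(case$struct, weights = c(w1 = 0, w2 = 0, w3 = 0))
  t2 <- predict_interface(case$struct, weights = c(w1 = 0, w2 = 0, w3 = 0))
  expect_identical(t1$members, t2$members)
  expect_true(all(t1$members %in% surface_residues(case$struct)))
  ranked <- attr(t1, "ranked")
  expect_gte(length(ranked), 1)
  # the returned patch attains the maximal score
  scores <- vapply(ranked, `[[`, numeric(1), "e_patch")
  expect_equal(t1$e_patch, max(scores))
})

test_that("a strongly planted high-propensity face is ranked first", {
  # interface heavily enriched in Met (high QIPI per reference area);
  # QIPI-only scoring must put the top patch on the planted face
  case <- toy_unbound_case(fixture_spec(seed = 56, n_per_side = 25,
                                        composition_bias = c(M = 40)))
  top <- predict_interface(case$struct, weights = c(w1 = 0, w2 = 0, w3 = 0))
  ranked <- attr(top, "ranked")
  cov_top <- evaluate_prediction(top, case$truth)$cov
  covs <- vapply(ranked, function(p)
    evaluate_prediction(p, case$truth)$cov, numeric(1))
  expect_gte(cov_top, max(covs) * 0.8)
  expect_gt(cov_top, 0.5)
})
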