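test_that("RIR reproduces the hand-evaluated two-type example", {
  pt <- compute_rir(c(A = 30, G = 10), c(A = 60, G = 140))
  expect_equal(pt$w[pt$key == "A"], 0.75)
  expect_equal(pt$W[pt$key == "A"], 0.3)
  expect_equal(pt$rir[pt$key == "A"], 2.5)
  expect_equal(round(pt$rir[pt$key == "G"], 3), 0.357)
  expect_equal(sum(pt$w), 1, tolerance = 1e-9)
  expect_equal(sum(pt$W), 1, tolerance = 1e-9)
})

test_that("identical compositions give unit RIR everywhere", {
  cts <- c(A = 12, M = 5, W = 3)
  pt <- compute_rir(cts, cts * 7)    # same proportions, different totals
  expect_true(all(abs(pt$rir - 1) < 1e-12))
})

test_that("RIR matches a brute-force recount on random residue lists", {
  set.seed(202)
  for (k in 1:20) {
    iface <- sample(ppiprop:::AA20, 50 + k, replace = TRUE)
    nonif <- sample(ppiprop:::AA20, 200 - k, replace = TRUE)
    oracle <- recount_rir(iface, nonif)
    pt <- compute_rir(table(iface), table(nonif))
    expect_equal(stats::setNames(pt$rir, pt$key), oracle$rir[pt$key])
    expect_equal(stats::setNames(pt$f, pt$key), oracle$f[pt$key])
  }
})

test_that("zero reference counts flag the RIR as undefined", {
  pt <- compute_rir(c(A = 5, W = 5), c(A = 10))
  expect_true(is.na(pt$rir[pt$key == "W"]))
  pt2 <- compute_rir(c(A = 5, W = 5), c(A = 10), pseudocount = 1)
  expect_false(any(is.na(pt2$rir)))
  expect_error(compute_rir(c(A = -1), c(A = 3)), "non-negative")
})

test_that("60-class counts marginalize exactly to 20- and 3-class tables", {
  anns <- lapply(c(31, 32, 33), function(sd) {
    toy <- make_toy_complex(fixture_spec(seed = sd, n_per_side = 20))
    cx <- assign_secondary_structure(read_structure(toy$pdb))
    extract_interface(complex_partition(cx, "A", "B"))
  })
  t20 <- rir_by_type(anns)
  both <- ss_and_class60_rir(anns)
  c60 <- both$class60
  parts <- do.call(rbind, strsplit(c60$key, ":", fixed = TRUE))
  # over SS states -> residue-type counts
  by_type <- rowsum(c60$f, parts[, 1])
  expect_equal(by_type[t20$key, 1], stats::setNames(t20$f, t20$key))
  # over residue types -> SS counts
  by_ss <- rowsum(c60$f, parts[, 2])
  expect_equal(by_ss[both$ss$key, 1],
               stats::setNames(both$ss$f, both$ss$key))
  expect_equal(sum(both$ss$w), 1, tolerance = 1e-9)
})

test_that("a planted coil-only interface depresses helix/strand RIR", {
  res <- rbind(
    annotation_residues("a", rep(ppiprop:::AA20, 3), "interface",
                        ss = "C"),
    annotation_residues("b", rep(ppiprop:::AA20, each = 6), "noninterface",
                        ss = rep(c("H", "E", "C"), 40))
  )
  res$res_id <- paste0(res$chain, ":", seq_len(nrow(res)), ":")
  both <- ss_and_class60_rir(fake_annotation(res))
  ss <- both$ss
  expect_gt(ss$rir[ss$key == "C"], 1)
  expect_true(is.na(ss$rir[ss$key == "H"]) || ss$rir[ss$key == "H"] < 1)
})

test_that("the ASA crossover threshold lands in the overlap region", {
  # rising interface density vs falling non-interface density on
  # [0, 60]: the two normalized histograms cross at 30 by construction
  set.seed(9)
  res <- rbind(
    annotation_residues("a", "M", "interface",
                        asa_unbound = 60 * sqrt(stats::runif(2000))),
    annotation_residues("b", "M", "noninterface",
                        asa_unbound = 60 * (1 - sqrt(stats::runif(2000))))
  )
  res$res_id <- paste0(res$chain, ":", seq_len(nrow(res)), ":")
  ac <- asa_threshold_and_rir(fake_annotation(res), "M")
  expect_gte(ac$A_t, 20)
  expect_lte(ac$A_t, 40)
  # at the exact crossover (30), (0.75/0.25)/(0.25/0.75) = 9
  expect_gt(ac$asa_rir, 3)
  expect_equal(ac$f_IS + ac$f_IL, 2000L)
})

test_that("identical ASA distributions give a near-unit ASA-RIR", {
  set.seed(10)
  asa <- stats::runif(4000, 0, 80)
  res <- rbind(
    annotation_residues("a", "L", "interface", asa_unbound = asa[1:2000]),
    annotation_residues("b", "L", "noninterface",
                        asa_unbound = asa[2001:4000])
  )
  res$res_id <- paste0(res$chain, ":", seq_len(nrow(res)), ":")
  ac <- asa_threshold_and_rir(fake_annotation(res), "L")
  expect_equal(ac$asa_rir, 1, tolerance = 0.25)  # sampling noise only
})

test_that("nearly separated ASA distributions give an extreme ASA-RIR", {
  # interface mass concentrated high on [25, 80], non-interface mass
  # low on [0, 35]: a thin overlap window around 25-35
  set.seed(11)
  n <- 5000   # the overlap window is thin; resolve it beyond noise
  res <- rbind(
    annotation_residues("a", "K", "interface",
                        asa_unbound = 25 + 55 * sqrt(stats::runif(n))),
    annotation_residues("b", "K", "noninterface",
                        asa_unbound = 35 * (1 - sqrt(stats::runif(n))))
  )
  res$res_id <- paste0(res$chain, ":", seq_len(nrow(res)), ":")
  ac <- asa_threshold_and_rir(fake_annotation(res), "K")
  # crossover inside the thin overlap window
  expect_gte(ac$A_t, 25)
  expect_lte(ac$A_t, 35)
  # brute-force recount at the reported threshold
  asa_int <- res$asa_unbound[res$class == "interface"]
  asa_non <- res$asa_unbound[res$class == "noninterface"]
  expect_equal(ac$f_IS, sum(asa_int < ac$A_t))
  expect_equal(ac$f_SL, sum(asa_non >= ac$A_t))
  expect_lt(ac$f_IS, 0.1 * n)
  expect_gt(ac$asa_rir, 5)
})

test_that("disjoint ASA supports flag the ASA-RIR undefined", {
  res <- rbind(
    annotation_residues("a", "K", "interface",
                        asa_unbound = seq(50, 80, length.out = 100)),
    annotation_residues("b", "K", "noninterface",
                        asa_unbound = seq(1, 30, length.out = 100))
  )
  res$res_id <- paste0(res$chain, ":", seq_len(nrow(res)), ":")
  ac <- asa_threshold_and_rir(fake_annotation(res), "K")
  expect_true(is.na(ac$asa_rir))   # f_IS = f_SL = 0 at the gap crossover
  expect_equal(ac$f_IS, 0L)
})
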