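# Distance matrix, patch growth against the distance-binned ASA
# thresholds, and identity-ratio merging.

# fabricate a distance matrix + matching minimal structure with given
# per-residue ASA
fake_dm <- function(ids, d, asa) {
  dimnames(d) <- list(ids, ids)
  dm <- structure(list(ids = ids, d = d), class = "spr_distmat")
  struct <- structure(list(
    residues = data.frame(res_id = ids, asa = asa,
                          stringsAsFactors = FALSE)
  ), class = "spr_structure")
  list(dm = dm, struct = struct)
}

test_that("side-chain distances use CA for glycine and cap at 25 A", {
  df <- rbind(
    # G1 at origin, G2 at 8 A: glycines -> CA-CA distance
    data.frame(chain = "A", resno = 1, elety = "CA", element = "C",
               resid3 = "GLY", x = 0, y = 0, z = 0),
    data.frame(chain = "A", resno = 2, elety = "CA", element = "C",
               resid3 = "GLY", x = 8, y = 0, z = 0),
    # ALA with CA far but CB close to residue 2
    data.frame(chain = "A", resno = 3, elety = c("CA", "CB"), element = "C",
               resid3 = "ALA", x = c(20, 11), y = 0, z = 0),
    # far-away glycine beyond the cap
    data.frame(chain = "A", resno = 4, elety = "CA", element = "C",
               resid3 = "GLY", x = 80, y = 0, z = 0)
  )
  s <- compute_asa(make_structure(df))
  dm <- sidechain_distance_matrix(s)
  expect_equal(unname(diag(dm$d)), rep(0, 4))
  expect_identical(dm$d, t(dm$d))
  expect_equal(dm$d["A:1:", "A:2:"], 8)       # CA-CA for Gly pair
  expect_equal(dm$d["A:2:", "A:3:"], 3)       # side-chain CB, not CA
  expect_equal(dm$d["A:1:", "A:4:"], 25)      # capped
  expect_true(all(dm$d <= 25))
})

test_that("patch growth follows the distance-binned ASA thresholds", {
  ids <- paste0("A:", 1:8, ":")
  d <- matrix(25, 8, 8)
  diag(d) <- 0
  # distances from the seed A:1:
  d[1, 2] <- d[2, 1] <- 6.0    # bin (5,7]: needs ASA > 20
  d[1, 3] <- d[3, 1] <- 6.0
  d[1, 4] <- d[4, 1] <- 1.5    # <= 2 A: unconditional
  d[1, 5] <- d[5, 1] <- 16.0   # beyond the last bin: never
  d[1, 6] <- d[6, 1] <- 5.0    # bin (2,5]: needs ASA > 0
  d[1, 7] <- d[7, 1] <- 13.5   # bin (13,15]: needs ASA > 100
  d[1, 8] <- d[8, 1] <- 13.5
  asa <- c(50, 25, 15, 0.5, 200, 2, 100, 101)
  fd <- fake_dm(ids, d, asa)
  p <- grow_patch("A:1:", fd$dm, fd$struct)
  expect_setequal(p$members,
                  c("A:1:", "A:2:", "A:4:", "A:6:", "A:8:"))
  expect_equal(p$seed, "A:1:")
  expect_error(grow_patch("A:99:", fd$dm, fd$struct), "not a surface")
})

test_that("raising an ASA threshold never adds patch members", {
  set.seed(55)
  n <- 25
  ids <- paste0("A:", seq_len(n), ":")
  pts <- matrix(stats::runif(2 * n, 0, 18), ncol = 2)
  d <- as.matrix(stats::dist(cbind(pts, 0)))
  fd <- fake_dm(ids, d, stats::runif(n, 0, 150))
  base <- spr_constants()$patch_growth
  for (row in seq_len(nrow(base))) {
    stricter <- base
    stricter$min_asa[row] <- stricter$min_asa[row] + 30
    for (seed_id in ids[1:5]) {
      p0 <- grow_patch(seed_id, fd$dm, fd$struct, base)
      p1 <- grow_patch(seed_id, fd$dm, fd$struct, stricter)
      expect_true(all(p1$members %in% p0$members))
    }
  }
})

test_that("one patch is generated per surface residue, in order", {
  case <- toy_unbound_case(fixture_spec(seed = 41, n_per_side = 15))
  surf <- surface_residues(case$struct)
  patches <- generate_patches(case$struct)
  expect_length(patches, length(surf))
  expect_equal(vapply(patches, `[[`, character(1), "seed"), surf)
  for (p in patches) expect_true(p$seed %in% p$members)
})

test_that("merging respects the identity-ratio threshold by domain size", {
  p1 <- ppiprop:::new_patch(paste0("A:", 1:10, ":"), seed = "A:1:")
  p2 <- ppiprop:::new_patch(paste0("A:", 3:12, ":"), seed = "A:3:")
  # overlap 8, min size 10 -> ratio 0.8
  merged <- merge_patches(list(p1, p2), domain_asa = 4000)
  expect_length(merged, 1)
  expect_setequal(merged[[1]]$members, paste0("A:", 1:12, ":"))
  expect_true(is.na(merged[[1]]$seed))

  p3 <- ppiprop:::new_patch(paste0("A:", 4:13, ":"), seed = "A:4:")
  # overlap 7 -> ratio 0.7 < 0.8 at domain ASA 4000: no merge ...
  expect_length(merge_patches(list(p1, p3), domain_asa = 4000), 2)
  # ... but 0.7 suffices for a 6000 A^2 domain
  expect_length(merge_patches(list(p1, p3), domain_asa = 6000), 1)
})

test_that("merging reaches a fixpoint and decreases the patch count", {
  set.seed(66)
  universe <- paste0("A:", 1:40, ":")
  patches <- lapply(1:12, function(k) {
    ppiprop:::new_patch(sort(sample(universe, sample(5:15, 1))),
                        seed = paste0("A:", k, ":"))
  })
  merged <- merge_patches(patches, domain_asa = 9000)
  expect_lte(length(merged), length(patches))
  # fixpoint: no admissible pair remains
  again <- merge_patches(merged, domain_asa = 9000)
  expect_equal(lapply(again, `[[`, "members"),
               lapply(merged, `[[`, "members"))
  # disjoint patches pass through untouched (as sets)
  disjoint <- list(ppiprop:::new_patch(paste0("A:", 1:5, ":")),
                   ppiprop:::new_patch(paste0("A:", 6:10, ":")))
  out <- merge_patches(disjoint, 4000)
  expect_setequal(
    vapply(out, function(p) paste(sort(p$members), collapse = "|"),
           character(1)),
    vapply(disjoint, function(p) paste(sort(p$members), collapse = "|"),
           character(1)))
})

test_that("the patch pipeline is deterministic", {
  case <- toy_unbound_case(fixture_spec(seed = 42, n_per_side = 15))
  run <- function() {
    patches <- generate_patches(case$struct)
    merged <- merge_patches(patches, total_asa(case$struct))
    lapply(merged, `[[`, "members")
  }
  expect_identical(run(), run())
})
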