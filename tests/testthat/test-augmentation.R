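ch4 <- function() {
  molecule(c("C", "H", "H", "H", "H"),
           rbind(c(0, 0, 0), c(1.09, 0, 0), c(-0.36, 1.03, 0),
                 c(-0.36, -0.51, 0.89), c(-0.36, -0.51, -0.89)),
           id = "ch4")
}

co2h2 <- function() {
  # worked example ordering: C O1 O2 H1 H2
  molecule(c("C", "O", "O", "H", "H"),
           rbind(c(0, 0, 0), c(1.2, 0, 0), c(-1.2, 0, 0),
                 c(0, 1.0, 0), c(0, -1.0, 0)),
           id = "co2h2")
}

test_that("shuffle 'none' is the identity", {
  mol <- fixture_molecule(60)
  out <- permute_atoms(mol, shuffle_spec("none"))
  expect_identical(out$symbols, mol$symbols)
  expect_identical(out$coords, mol$coords)
})

test_that("groups shuffle never changes the element at any position", {
  spec <- shuffle_spec("groups")
  for (seed in 61:64) {
    mol <- fixture_molecule(seed)
    set.seed(seed)
    for (i in 1:25) {
      out <- permute_atoms(mol, spec)
      expect_identical(out$symbols, mol$symbols)
    }
  }
})

test_that("partial shuffle never crosses the heavy/hydrogen boundary", {
  spec <- shuffle_spec("partial")
  for (seed in 65:68) {
    mol <- fixture_molecule(seed)
    is_h <- mol$symbols == "H"
    set.seed(seed)
    for (i in 1:25) {
      out <- permute_atoms(mol, spec)
      expect_identical(out$symbols == "H", is_h)
    }
  }
})

test_that("CH4 under groups yields exactly 24 orderings, carbon fixed", {
  mol <- ch4()
  perms <- character(0)
  for (seed in 1:500) {
    set.seed(seed)
    p <- draw_permutation(mol, shuffle_spec("groups"))
    expect_equal(p[1], 1L)               # the lone carbon cannot move
    perms <- c(perms, paste(p, collapse = ","))
  }
  expect_equal(length(unique(perms)), 24L)    # 4! hydrogen arrangements
  expect_equal(n_distinct_orderings(mol, shuffle_spec("groups")), 24)
})

test_that("the worked shuffle examples are reachable", {
  mol <- co2h2()
  # groups: C O1 O2 H1 H2 -> C O2 O1 H1 H2
  target_g <- c(1L, 3L, 2L, 4L, 5L)
  # partial: C O1 O2 H1 H2 -> O1 O2 C H2 H1
  target_p <- c(2L, 3L, 1L, 5L, 4L)
  seen_g <- seen_p <- FALSE
  for (seed in 1:3000) {
    set.seed(seed)
    if (identical(draw_permutation(mol, shuffle_spec("groups")), target_g)) seen_g <- TRUE
    set.seed(seed)
    if (identical(draw_permutation(mol, shuffle_spec("partial")), target_p)) seen_p <- TRUE
    if (seen_g && seen_p) break
  }
  expect_true(seen_g)
  expect_true(seen_p)
  # and the groups draw can never produce the partial target (C moved)
  expect_equal(n_distinct_orderings(mol, shuffle_spec("groups")), 4)      # 2! * 2!
  expect_equal(n_distinct_orderings(mol, shuffle_spec("partial")), 12)    # 3! * 2!
  expect_equal(n_distinct_orderings(mol, shuffle_spec("full")), 120)
  expect_equal(n_distinct_orderings(mol, shuffle_spec("none")), 1)
})

test_that("augmentation planning reproduces the data-point arithmetic", {
  expect_equal(plan_augmentation(120000, 4)$total_points, 480000)
  expect_equal(plan_augmentation(20000, 16)$total_points, 320000)
  expect_equal(plan_augmentation(7, 1)$total_points, 7)
  expect_warning(plan_augmentation(10, 4, shuffle_kind = "none"), "duplicate")
})

test_that("database subsetting draws floor(n/N) molecules, seeded", {
  mols <- lapply(1:40, function(i) fixture_molecule(100 + i))
  expect_identical(subset_database(mols, 1), mols)
  set.seed(3); a <- subset_database(mols, 6)
  expect_length(a, 6L)    # floor(40/6)
  set.seed(3); b <- subset_database(mols, 6)
  expect_identical(a, b)
  expect_error(subset_database(mols[1:3], 4), "empty subset")
})

test_that("dataset generation counts, labels and determinism hold", {
  mols <- lapply(1:10, function(i) fixture_molecule(200 + i))
  dir1 <- tempfile(); dir2 <- tempfile()
  cfg <- encoding_config("A", 32, "black")
  set.seed(11)
  ds1 <- generate_dataset(mols, dir1, cfg, shuffle_spec("groups"), k = 4)
  expect_equal(nrow(ds1$manifest), 40L)
  expect_length(list.files(dir1, pattern = "png$"), 40L)
  # label preservation: every image inherits its molecule's label
  labels <- sapply(mols, `[[`, "label")
  names(labels) <- sapply(mols, `[[`, "id")
  expect_equal(ds1$manifest$label, unname(labels[ds1$manifest$molecule_id]))
  # byte-identical under the same seed
  set.seed(11)
  ds2 <- generate_dataset(mols, dir2, cfg, shuffle_spec("groups"), k = 4)
  expect_identical(ds1$manifest$label, ds2$manifest$label)
  f1 <- list.files(dir1, pattern = "png$", full.names = TRUE)
  f2 <- list.files(dir2, pattern = "png$", full.names = TRUE)
  expect_identical(lapply(f1, function(f) readBin(f, "raw", 1e5)),
                   lapply(f2, function(f) readBin(f, "raw", 1e5)))
})

test_that("symmetric molecules exhaust orderings and duplicate gracefully", {
  h2 <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.74)), id = "h2",
                 label = 10.2)
  set.seed(4)
  expect_warning(
    ds <- generate_dataset(list(h2), NULL, encoding_config("A", 8, "black"),
                           shuffle_spec("groups"), k = 4, write_png = FALSE),
    "distinct orderings")
  expect_equal(nrow(ds$manifest), 4L)
  px <- lapply(ds$images, `[[`, "pixels")
  for (i in 2:4) expect_identical(px[[i]], px[[1]])  # swapping identical atoms
})

test_that("constitutional isomer fixtures stay distinguishable under shuffling", {
  # same formula C2H6O, different connectivity: ethanol-like vs ether-like
  ethanol <- molecule(c("C", "C", "O", "H", "H", "H", "H", "H", "H"),
    rbind(c(0, 0, 0), c(1.52, 0, 0), c(2.2, 1.2, 0),
          c(-0.5, 0.9, 0.3), c(-0.5, -0.8, 0.4), c(-0.4, -0.2, -1.0),
          c(1.9, -0.6, 0.8), c(1.9, -0.4, -0.9), c(3.1, 1.1, 0.3)),
    id = "ethanol")
  ether <- molecule(c("C", "O", "C", "H", "H", "H", "H", "H", "H"),
    rbind(c(0, 0, 0), c(1.41, 0, 0), c(2.1, 1.2, 0),
          c(-0.4, 0.5, 0.9), c(-0.4, 0.5, -0.9), c(-0.4, -1.0, 0),
          c(1.8, 1.8, 0.8), c(1.8, 1.7, -0.9), c(3.2, 1.1, 0.1)),
    id = "ether")
  cfg <- encoding_config("A", 12, "black")
  set.seed(8)
  imgs_a <- replicate(10, encode_molecule(permute_atoms(ethanol, shuffle_spec("groups")), cfg)$pixels,
                      simplify = FALSE)
  imgs_b <- replicate(10, encode_molecule(permute_atoms(ether, shuffle_spec("groups")), cfg)$pixels,
                      simplify = FALSE)
  for (a in imgs_a) for (b in imgs_b) expect_false(identical(a, b))
})
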