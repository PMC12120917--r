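test_that("normalization maps endpoints, constants and fixed ranges correctly", {
  expect_equal(normalize_matrix(matrix(0, 3, 3)), matrix(0, 3, 3))
  m <- matrix(c(0, 5, 10, 5), 2, 2)
  expect_equal(normalize_matrix(m), matrix(c(0, 127.5, 255, 127.5), 2, 2))

  set.seed(9)
  r <- matrix(runif(25, 0, 4), 5, 5)
  hi <- 2 * max(r)
  out <- normalize_matrix(r, list(scheme = "fixed", lo = 0, hi = hi))
  expect_equal(out, 255 * (r - 0) / (hi - 0))   # scalar formula

  expect_error(normalize_matrix(r, list(scheme = "fixed", lo = 1, hi = 1)),
               "hi > lo")
  expect_error(encoding_config(normalization = list(scheme = "fixed",
                                                    ranges = list(distance = c(2, 1)))),
               "hi > lo")
})

test_that("generation types differ pairwise in exactly one channel plane", {
  pairs <- list(c("A", "C"), c("A", "B"), c("B", "F"), c("E", "F"), c("C", "D"))
  params <- load_pair_params()
  for (seed in 31:36) {
    mol <- fixture_molecule(seed, n_heavy = sample(3:7, 1))
    planes <- lapply(LETTERS[1:6], function(g) {
      compose_channels(mol, encoding_config(g, canvas_size = 32), params = params)
    })
    names(planes) <- LETTERS[1:6]
    for (pr in pairs) {
      same <- sapply(1:3, function(ch) {
        identical(planes[[pr[1]]][, , ch], planes[[pr[2]]][, , ch])
      })
      expect_equal(sum(!same), 1L,
                   info = sprintf("pair %s-%s seed %d", pr[1], pr[2], seed))
    }
  }
})

test_that("type E planes are diagonal-only where the layout says so", {
  mol <- fixture_molecule(40, n_heavy = 4)
  raw <- compose_channels(mol, encoding_config("E"))
  off <- row(raw[, , 1]) != col(raw[, , 1])
  expect_true(all(raw[, , 1][off] == 0))  # red: ionization, diagonal only
  expect_true(all(raw[, , 3][off] == 0))  # blue: atomic number, diagonal only
  expect_true(any(raw[, , 2][off] != 0))  # green: full Coulomb fills off-diagonal
})

test_that("black margin zero-fills outside the top-left block", {
  mol <- fixture_molecule(41, n_heavy = 1)  # CH4-like, N = 5
  n <- length(mol$symbols)
  cfg <- encoding_config("A", 32, "black", "fixed", quantize = FALSE)
  img <- encode_molecule(mol, cfg)
  px <- img$pixels
  expect_equal(dim(px), c(32, 32, 3))
  expect_true(all(px[(n + 1):32, , ] == 0))
  expect_true(all(px[, (n + 1):32, ] == 0))
  raw <- compose_channels(mol, cfg)
  expect_equal(px[1:n, 1:n, ], raw)
})

test_that("average margin fills with the per-channel block mean", {
  mol <- fixture_molecule(42, n_heavy = 2)
  n <- length(mol$symbols)
  cfg <- encoding_config("A", 32, "average", "fixed", quantize = FALSE)
  raw <- compose_channels(mol, cfg)
  px <- place_on_canvas(raw, cfg)$pixels
  for (ch in 1:3) {
    m <- sum(raw[, , ch]) / (n * n)   # independent mean computation
    margin <- px[(n + 1):32, , ch]
    expect_equal(max(abs(margin - m)), 0, tolerance = 1e-12)
    expect_true(all(margin == margin[1]))   # uniform fill
  }
})

test_that("a block larger than the canvas errors in non-resize modes", {
  mol <- fixture_molecule(43, n_heavy = 9)   # N > 8 after H fill
  cfg <- encoding_config("A", 8, "black")
  expect_error(encode_molecule(mol, cfg), "exceeds the canvas|exceeds canvas|N = ")
  ok <- encode_molecule(mol, encoding_config("A", 8, "resize"))
  expect_equal(dim(ok$pixels), c(8, 8, 3))
})

test_that("resize with N = S is the identity; offsets are forced fixed", {
  mol <- fixture_molecule(44, n_heavy = 3)
  n <- length(mol$symbols)
  cfg <- encoding_config("A", n, "resize", "random", quantize = FALSE)
  expect_equal(cfg$offset_mode, "fixed")
  raw <- compose_channels(mol, cfg)
  expect_equal(place_on_canvas(raw, cfg)$pixels,
               array(raw, dim = c(n, n, 3)))
  # N = S degenerate margin: all modes equal the raw block
  for (mode in c("black", "average")) {
    cfg2 <- encoding_config("A", n, mode, "random", quantize = FALSE)
    expect_equal(place_on_canvas(raw, cfg2)$pixels, raw)
  }
})

test_that("bilinear resize matches a per-pixel reference implementation", {
  set.seed(7)
  plane <- matrix(runif(36, 0, 255), 6, 6)
  s <- 13
  ref <- matrix(0, s, s)
  for (i in 0:(s - 1)) {
    for (j in 0:(s - 1)) {
      sr <- min(max((i + 0.5) * 6 / s - 0.5, 0), 5)
      sc <- min(max((j + 0.5) * 6 / s - 0.5, 0), 5)
      r0 <- floor(sr); c0 <- floor(sc)
      r1 <- min(r0 + 1, 5); c1 <- min(c0 + 1, 5)
      fr <- sr - r0; fc <- sc - c0
      ref[i + 1, j + 1] <- plane[r0 + 1, c0 + 1] * (1 - fr) * (1 - fc) +
        plane[r1 + 1, c0 + 1] * fr * (1 - fc) +
        plane[r0 + 1, c1 + 1] * (1 - fr) * fc +
        plane[r1 + 1, c1 + 1] * fr * fc
    }
  }
  expect_equal(bilinear_resize(plane, s), ref, tolerance = 1e-12)
})

test_that("random offsets are uniform over the placement grid", {
  mol <- fixture_molecule(45, n_heavy = 1)   # N = 5
  cfg <- encoding_config("A", 12, "black", "random", quantize = FALSE)
  raw <- compose_channels(mol, cfg)
  set.seed(123)
  draws <- t(replicate(4000, place_on_canvas(raw, cfg)$offset))
  grid <- 12 - 5 + 1
  expect_true(all(draws >= 0 & draws <= grid - 1))
  counts <- table(factor(draws[, 1] * grid + draws[, 2], levels = 0:(grid^2 - 1)))
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 1e-4)
})

test_that("encoding is deterministic and quantization yields integers", {
  mol <- fixture_molecule(46)
  cfg <- encoding_config("B", 32, "black", "random")
  set.seed(99); a <- encode_molecule(mol, cfg)
  set.seed(99); b <- encode_molecule(mol, cfg)
  expect_identical(a$pixels, b$pixels)
  expect_true(all(a$pixels == floor(a$pixels)))
  expect_true(all(a$pixels >= 0 & a$pixels <= 255))
})

test_that("encoding a permuted molecule permutes the image block", {
  cfg <- encoding_config("A", 32, "black", "fixed", quantize = FALSE)
  for (seed in 47:50) {
    mol <- fixture_molecule(seed, n_heavy = 3)
    n <- length(mol$symbols)
    set.seed(seed)
    p <- sample.int(n)
    a <- encode_molecule(mol, cfg)$pixels[1:n, 1:n, ]
    b <- encode_molecule(permute_atoms(mol, perm = p), cfg)$pixels[1:n, 1:n, ]
    expect_identical(b, a[p, p, ])
  }
})

test_that("full encoder matches the naive per-pixel reference on small molecules", {
  for (seed in 51:56) {
    mol <- fixture_molecule(seed, n_heavy = 1)
    if (length(mol$symbols) > 6) next
    cfg <- encoding_config("A", 8, "black", "fixed", quantize = FALSE)
    got <- encode_molecule(mol, cfg)$pixels
    ref <- naive_encode_A_black(mol, 8)
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("diagonal red pixels of type A are the normalized ionization energies", {
  mol <- molecule(c("C", "H", "O"), rbind(c(0, 0, 0), c(1.1, 0, 0), c(0, 1.4, 0)))
  cfg <- encoding_config("A", 3, "black", quantize = FALSE)
  px <- encode_molecule(mol, cfg)$pixels
  ion <- c(11.260, 13.598, 13.618)
  expect_equal(diag(px[, , 1]), 255 * (ion - min(ion)) / (max(ion) - min(ion)))
})

test_that("config fingerprints distinguish configs and are stable", {
  a <- config_fingerprint(encoding_config("A"))
  b <- config_fingerprint(encoding_config("B"))
  expect_match(a, "^[0-9a-f]{8}$")
  expect_false(a == b)
  expect_identical(a, config_fingerprint(encoding_config("A")))
})
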