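# Receptor reading, residue contact consensus maps, ligand RMSD, funnels.

toySystem <- function() fixture("toysystem", function() {
  dir <- file.path(tempdir(), "toy_receptor")
  makeToyReceptorAndPoses(dir, nResidues = 8L, nCompounds = 10L,
                          geometry = "funnel", nPoses = 30L, seed = 5L)
})

test_that("toy PDB round-trips through the receptor reader", {
  sys <- toySystem()
  rec <- readReceptorPdb(sys$receptorPath)
  expect_equal(nrow(rec$residues), 8L)
  expect_equal(rec$residues$resno, 1:8)
  expect_true(all(vapply(rec$coords, nrow, integer(1)) == 3L))
})

test_that("contact map equals the planted ground truth and brute force", {
  sys <- toySystem()
  rec <- readReceptorPdb(sys$receptorPath)
  poses <- readPoseSdf(sys$posesPath)
  cm <- residueContactMap(rec, poses, cutoff = 4.0)
  expect_equal(cm$count, sys$truth$count)
  # independent all-pairs distance check
  brute <- integer(nrow(rec$residues))
  for (r in seq_along(brute)) {
    n <- 0L
    for (i in seq_len(nrow(poses))) {
      touched <- FALSE
      for (a in seq_len(nrow(poses$coords[[i]]))) {
        for (b in seq_len(nrow(rec$coords[[r]]))) {
          if (sqrt(sum((poses$coords[[i]][a, ] -
                          rec$coords[[r]][b, ])^2)) <= 4.0)
            touched <- TRUE
        }
      }
      if (touched) n <- n + 1L
    }
    brute[r] <- n
  }
  expect_equal(cm$count, brute)
})

test_that("the 4 A cutoff is inclusive at 3.9 and exclusive at 4.1", {
  rec <- structure(list(
    sourceId = "unit", residues = data.frame(
      chain = "A", resno = 1L, insert = "", resid = "GLY",
      stringsAsFactors = FALSE),
    coords = list(matrix(c(0, 0, 0), 1))), class = "ReceptorStructure")
  mkpose <- function(z, key) {
    df <- data.frame(molecule_key = key, pose_index = 1L,
                     interface_delta = -12, stringsAsFactors = FALSE)
    df$coords <- list(matrix(c(0, 0, z), 1))
    df
  }
  inMap <- residueContactMap(rec, mkpose(3.9, "in"))
  outMap <- residueContactMap(rec, mkpose(4.1, "out"))
  expect_equal(inMap$count, 1L)
  expect_equal(outMap$count, 0L)
  # five atoms in range still count the compound once
  multi <- data.frame(molecule_key = "m", pose_index = 1L,
                      interface_delta = -12, stringsAsFactors = FALSE)
  multi$coords <- list(matrix(rep(c(0, 0, 2), 5), ncol = 3, byrow = TRUE))
  expect_equal(residueContactMap(rec, multi)$count, 1L)
})

test_that("contact counts fall into the published bins", {
  rec <- structure(list(
    sourceId = "unit", residues = data.frame(
      chain = "A", resno = 1:5, insert = "", resid = "GLY",
      stringsAsFactors = FALSE),
    coords = lapply(1:5, function(i) matrix(c(100 * i, 0, 0), 1))),
    class = "ReceptorStructure")
  counts <- c(600L, 450L, 300L, 150L, 50L)
  poses <- do.call(rbind, lapply(seq_len(600), function(i) {
    df <- data.frame(molecule_key = paste0("c", i), pose_index = 1L,
                     interface_delta = -12, stringsAsFactors = FALSE)
    near <- which(counts >= i)
    xyz <- if (length(near))
      matrix(c(100 * near, rep(0, 2 * length(near))), ncol = 3)
    else matrix(c(0, 0, 9999), 1)
    df$coords <- list(xyz)
    df
  }))
  cm <- residueContactMap(rec, poses)
  expect_equal(cm$count, counts)
  expect_equal(as.character(cm$bin),
               c(">500", "400-500", "200-400", "100-200", "<=100"))
})

test_that("ligand RMSD is exact on translations and matches the formula", {
  set.seed(12)
  a <- matrix(rnorm(30), ncol = 3)
  expect_equal(ligandRmsd(a, a), 0)
  shift <- a; shift[, 1] <- shift[, 1] + 3
  expect_equal(ligandRmsd(a, shift), 3)
  b <- matrix(rnorm(30), ncol = 3)
  direct <- sqrt(sum((a - b)^2) / nrow(a))
  expect_equal(ligandRmsd(a, b), direct, tolerance = 1e-9)
  expect_error(ligandRmsd(a, b[1:5, ]), "mismatch")
  # metric properties on sampled triples
  for (i in 1:10) {
    x <- matrix(rnorm(15), ncol = 3); y <- matrix(rnorm(15), ncol = 3)
    z <- matrix(rnorm(15), ncol = 3)
    expect_equal(ligandRmsd(x, y), ligandRmsd(y, x))
    expect_lte(ligandRmsd(x, z),
               ligandRmsd(x, y) + ligandRmsd(y, z) + 1e-12)
  }
})

test_that("funnel tables respect the score floor and funnel geometry", {
  sys <- toySystem()
  fun <- readPoseSdf(sys$funnelPath)
  ft <- funnelTable(fun, scoreFloor = -10)
  expect_equal(nrow(ft), nrow(fun))
  expect_true(!is.unsorted(ft$interface_delta))
  # RMSD populated exactly at or below the floor
  expect_identical(is.na(ft$rmsd_to_best), ft$interface_delta > -10)
  # a pose at -9 REU is excluded from RMSD computation
  expect_true(all(is.na(ft$rmsd_to_best[ft$interface_delta > -10])))
  # planted funnel: RMSD grows as scores worsen
  ok <- !is.na(ft$rmsd_to_best)
  rho <- stats::cor(ft$interface_delta[ok], ft$rmsd_to_best[ok],
                    method = "spearman")
  expect_gt(rho, 0.5)
  # identical coordinates give all-zero RMSD
  flat <- fun
  flat$coords <- rep(list(fun$coords[[1]]), nrow(fun))
  ft0 <- funnelTable(flat, scoreFloor = 0)
  expect_true(all(ft0$rmsd_to_best == 0))
})

test_that("scatter geometry shows no RMSD-score correlation", {
  dir <- file.path(tempdir(), "toy_scatter")
  sys <- makeToyReceptorAndPoses(dir, nResidues = 4L, nCompounds = 4L,
                                 geometry = "scatter", nPoses = 40L,
                                 seed = 9L)
  ft <- funnelTable(readPoseSdf(sys$funnelPath), scoreFloor = 0)
  rho <- stats::cor(ft$interface_delta, ft$rmsd_to_best,
                    method = "spearman")
  expect_lt(abs(rho), 0.45)
})
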