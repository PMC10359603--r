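# PDB ensemble reading, Kabsch superposition, ensemble RMSD.

two_model_pdb <- function() {
  c("HEADER    TEST",
    "MODEL        1",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA BALA A   1       9.000   9.000   9.000  1.00  0.00           C",
    "ATOM      4  H   ALA A   1       0.500   0.800   0.000  1.00  0.00           H",
    "ATOM      5  CA  GLY A   2       2.000   1.500   0.250  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  N   ALA A   1       0.100   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.558   0.000   0.000  1.00  0.00           C",
    "ATOM      5  CA  GLY A   2       2.100   1.500   0.250  1.00  0.00           C",
    "ENDMDL",
    "END")
}

test_that("read_ensemble parses models, altlocs, hydrogens and errors", {
  ens <- read_ensemble(two_model_pdb())
  expect_s3_class(ens, "structure_ensemble")
  expect_length(ens$models, 2L)
  m1 <- ens$models[[1]]
  expect_equal(nrow(m1), 3L)            # altloc B and hydrogen dropped
  expect_equal(m1$atom, c("N", "CA", "CA"))
  expect_equal(m1$resi, c(1L, 1L, 2L))
  expect_equal(m1$x, c(0, 1.458, 2.0))
  # no MODEL records: a single model by PDB convention
  single <- grep("^(MODEL|ENDMDL)", two_model_pdb()[1:8], invert = TRUE,
                 value = TRUE)
  expect_length(read_ensemble(single)$models, 1L)
  bad <- two_model_pdb()
  bad[3] <- paste0(substr(bad[3], 1, 30), "   xx.xxx", substr(bad[3], 40, 80))
  expect_error(read_ensemble(bad), "line 3")
})

test_that("PDB writing round-trips through read_ensemble", {
  ens <- gen_ensemble(n_models = 3, n_res = 10, seed = 4)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(ens, f)
  back <- read_ensemble(f)
  expect_length(back$models, 3L)
  expect_equal(back$models[[2]]$x, ens$models[[2]]$x, tolerance = 1e-3)
  expect_identical(back$models[[1]]$atom, ens$models[[1]]$atom)
})

test_that("kabsch: identity, rigid motions and symmetry", {
  set.seed(1)
  a <- matrix(rnorm(30), ncol = 3)
  k <- kabsch(a, a)
  expect_equal(k$rmsd, 0, tolerance = 1e-12)
  expect_equal(k$rotation, diag(3), tolerance = 1e-9)
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3)  # 90 deg about z
  b <- a %*% Rz + matrix(c(3, -2, 5), nrow(a), 3, byrow = TRUE)
  expect_equal(kabsch(a, b)$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(kabsch(a, b)$rotation), 1, tolerance = 1e-9)
  c2 <- matrix(rnorm(30), ncol = 3)
  expect_equal(kabsch(a, c2)$rmsd, kabsch(c2, a)$rmsd, tolerance = 1e-9)
  expect_error(kabsch(a[1:2, ], a[1:2, ]), "3 points")
  col <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch(col, col + 1), "degenerate")
})

test_that("kabsch matches brute-force quaternion search", {
  set.seed(2)
  for (i in 1:10) {
    a <- matrix(rnorm(30), ncol = 3)
    b <- matrix(rnorm(30), ncol = 3)
    exact <- kabsch(a, b)$rmsd
    brute <- oracle_superpose_rmsd(a, b)
    # Kabsch is the optimum: brute search can only approach from above
    expect_gte(brute, exact - 1e-9)
    expect_lt(brute - exact, 1e-3)
  }
})

test_that("ensemble_rmsd: identical models give zero under both conventions", {
  m <- gen_ensemble(n_models = 1, n_res = 8, sigma = 0, seed = 1)$models[[1]]
  ens <- structure(list(models = list(m, m, m)),
                   class = "structure_ensemble")
  st <- ensemble_rmsd(ens, residues = 1:8)
  expect_equal(st$to_mean, 0, tolerance = 1e-12)
  expect_equal(st$pairwise, 0, tolerance = 1e-12)
})

test_that("two-model single-atom displacement follows the d/sqrt(n) closed form", {
  m <- gen_ensemble(n_models = 1, n_res = 10, sigma = 0, seed = 3)$models[[1]]
  d <- 0.01
  m2 <- m
  m2$x[17] <- m2$x[17] + d
  ens <- structure(list(models = list(m, m2)),
                   class = "structure_ensemble")
  st <- ensemble_rmsd(ens, residues = 1:10)
  n_atoms <- nrow(m)
  expect_equal(st$pairwise, d / sqrt(n_atoms), tolerance = 0.03)
})

test_that("RMSD statistics are rigid-motion invariant and ordered", {
  ens <- gen_ensemble(n_models = 6, n_res = 20, seed = 9)
  st <- ensemble_rmsd(ens, residues = 3:18)
  expect_gte(st$pairwise, st$to_mean)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- ens
  moved$models <- lapply(ens$models, function(df) {
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% R
    df$x <- xyz[, 1] + 11; df$y <- xyz[, 2] - 4; df$z <- xyz[, 3] + 2
    df
  })
  st2 <- ensemble_rmsd(moved, residues = 3:18)
  expect_equal(st2$to_mean, st$to_mean, tolerance = 1e-9)
  expect_equal(st2$pairwise, st$pairwise, tolerance = 1e-9)
})

test_that("missing residues or atoms fail loudly", {
  ens <- gen_ensemble(n_models = 3, n_res = 10, seed = 5)
  expect_error(ensemble_rmsd(ens, residues = 5:12), "missing")
  ens$models[[2]] <- ens$models[[2]][-8, ]
  expect_error(ensemble_rmsd(ens, residues = 1:10), "model 2")
})

test_that("synthetic stand-in ensemble has the stated precision scale", {
  # synthetic emulation of a 20-model solution ensemble whose ordered
  # core overlays at ~0.36 A; NOT the deposited ensemble
  ens <- gen_ensemble(seed = 101)
  expect_length(ens$models, 20L)
  st <- ensemble_rmsd(ens, residues = 6:72)
  expect_gt(st$to_mean, 0.36 - 0.15)
  expect_lt(st$to_mean, 0.36 + 0.15)
  # disordered termini scatter far more than the core
  st_term <- ensemble_rmsd(ens, residues = c(1:5, 75:83))
  expect_gt(st_term$to_mean, 3 * st$to_mean)
})
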