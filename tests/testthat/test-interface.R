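# end-to-end checks of the command-line front end (thin layer over the
# package functions)

cliPath <- function() system.file("cli", "y90dose.R",
                                  package = "Y90dosimetry")

runCli <- function(...) {
  rscript <- file.path(R.home("bin"), "Rscript")
  # make sure the child process sees the same library tree as this session
  old <- Sys.getenv("R_LIBS", unset = NA)
  Sys.setenv(R_LIBS = paste(.libPaths(), collapse = .Platform$path.sep))
  on.exit(if (is.na(old)) Sys.unsetenv("R_LIBS")
          else Sys.setenv(R_LIBS = old))
  out <- suppressWarnings(system2(rscript, c(cliPath(), ...),
                                  stdout = TRUE, stderr = TRUE))
  list(status = attr(out, "status") %||% 0L, output = out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the CLI reproduces the worked partition-model example", {
  f <- tempfile(fileext = ".json")
  r <- runCli("compartmental", "--activity", "0.6", "--lsf", "10.7",
              "--tnr", "1.2", "--vtl", "18", "--vnlt", "410",
              "--vnlw", "1434", "--out", f)
  expect_equal(r$status, 0L)
  expect_true(any(grepl("D_TL = 74 Gy", r$output, fixed = TRUE)))
  parsed <- jsonlite::read_json(f)
  expect_equal(round(parsed$D_mean_TL_Gy), 74)
})

test_that("phantom -> compartmental -> voxelwise -> compare runs end-to-end", {
  d <- tempfile(); dir.create(d)
  expect_equal(runCli("phantom", "--out", d, "--seed", "5")$status, 0L)
  expect_true(file.exists(file.path(d, "counts.nii.gz")))
  truth <- jsonlite::read_json(file.path(d, "truth.json"))

  cj <- file.path(d, "comp.json")
  r2 <- runCli("compartmental", "--counts", file.path(d, "counts.nii.gz"),
               "--labels", file.path(d, "labels.nii.gz"),
               "--roles", file.path(d, "roles.json"),
               "--activity", "1.3", "--lsf", as.character(truth$lsf_percent),
               "--out", cj)
  expect_equal(r2$status, 0L)
  comp <- jsonlite::read_json(cj)
  expect_equal(comp$TNR, truth$TNR, tolerance = 1e-6)

  vd <- file.path(d, "vox")
  r3 <- runCli("voxelwise", "--counts", file.path(d, "counts.nii.gz"),
               "--labels", file.path(d, "labels.nii.gz"),
               "--roles", file.path(d, "roles.json"),
               "--activity", "1.3", "--lsf", as.character(truth$lsf_percent),
               "--out", vd)
  expect_equal(r3$status, 0L)
  expect_true(file.exists(file.path(vd, "dose_ldm.nii.gz")))

  cmp <- file.path(d, "cmp.json")
  r4 <- runCli("compare", "--a", file.path(vd, "dose_dpk.nii.gz"),
               "--b", file.path(vd, "dose_ldm.nii.gz"),
               "--labels", file.path(d, "labels.nii.gz"),
               "--roles", file.path(d, "roles.json"),
               "--voi", "WL", "--out", cmp)
  expect_equal(r4$status, 0L)
  agr <- jsonlite::read_json(cmp)
  expect_lt(agr$nmse_percent, 100)
  expect_gt(agr$lin_ccc, 0.5)
})

test_that("repeated CLI runs with one seed give byte-identical reports", {
  d1 <- tempfile(); d2 <- tempfile()
  runCli("phantom", "--out", d1, "--seed", "11", "--noise")
  runCli("phantom", "--out", d2, "--seed", "11", "--noise")
  expect_identical(readLines(file.path(d1, "truth.json")),
                   readLines(file.path(d2, "truth.json")))
  expect_identical(readBin(file.path(d1, "counts.nii.gz"), "raw", 1e6),
                   readBin(file.path(d2, "counts.nii.gz"), "raw", 1e6))
})

test_that("validation failures exit non-zero with a diagnostic", {
  r <- runCli("lsf", "--anterior", "/nonexistent.nii",
              "--posterior", "/nonexistent.nii",
              "--lung", "/nonexistent.nii", "--liver", "/nonexistent.nii")
  expect_equal(r$status, 1L)
  expect_true(any(grepl("error", r$output)))
  expect_equal(runCli("frobnicate")$status, 1L)
})
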