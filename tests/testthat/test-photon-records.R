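test_that("gate assignment follows detector band and PIE window", {
  win <- gate_windows()
  res <- 1 / (26.67e6 * 4096)
  nano_at <- function(t_s) as.integer(t_s / res)
  ps <- photon_stream(
    macrotime = c(10, 20, 30, 40, 50),
    nanotime = c(nano_at(5e-9), nano_at(25e-9), nano_at(5e-9),
                 nano_at(25e-9), nano_at(5e-9)),
    detector = c("Bpar", "Rperp", "Rpar", "Bpar", "Bperp"),
    windows = win)
  expect_equal(gate_labels(ps),
               c("BBpar", "RRperp", "BRpar", "discarded", "BBperp"))
})

test_that("gate counts partition random streams and assignment is idempotent", {
  for (seed in 1:5) {
    ps <- tiny_stream(500, seed)
    expect_equal(sum(gate_counts(ps)), length(ps))
    again <- assign_pie_gates(ps, gate_windows())
    expect_identical(again$gate, ps$gate)
  }
})

test_that("gate assignment is independent of photon order", {
  ps <- tiny_stream(300, 7)
  o <- order(ps$nanotime)  # a different, still macrotime-breaking order? keep sorted macro
  ## permute microtimes/detectors together with a stable macrotime resort
  sub <- ps[o[order(ps$macrotime[o])]]
  sub <- assign_pie_gates(sub, gate_windows())
  expect_equal(sort(table(gate_labels(sub))), sort(table(gate_labels(ps))))
})

test_that("photon stream validates its invariants", {
  expect_error(photon_stream(c(5, 3), c(0L, 0L), c("Bpar", "Bpar")),
               "nondecreasing")
  expect_error(photon_stream(c(1, 2), c(0L, 5000L), c("Bpar", "Bpar")),
               "nanotime")
  expect_error(photon_stream(1, 0L, "Xpar"), "detector")
  expect_error(gate_windows(donor = c(0, 20e-9), acceptor = c(18e-9, 37.5e-9)),
               "overlap")
})

test_that("TSV round trip preserves integer fields exactly", {
  ps <- tiny_stream(1000, 3)
  path <- tempfile(fileext = ".tsv")
  write_photons(ps, path)
  back <- read_photons(path)
  expect_identical(back$macrotime, ps$macrotime)
  expect_identical(back$nanotime, ps$nanotime)
  expect_identical(back$detector, ps$detector)
  expect_identical(back$gate, ps$gate)          # gates recomputed, equal
  expect_equal(back$sync_rate_hz, ps$sync_rate_hz)
  unlink(path)
})

test_that("empty and singleton streams round-trip", {
  e <- photon_stream(numeric(0), integer(0), character(0), windows = gate_windows())
  path <- tempfile(fileext = ".tsv")
  write_photons(e, path)
  back <- read_photons(path)
  expect_equal(length(back), 0L)
  expect_equal(back$sync_rate_hz, 26.67e6)

  one <- photon_stream(floor(0.5 * 26.67e6), as.integer(3e-9 * 26.67e6 * 4096),
                       "Bpar", windows = gate_windows())
  write_photons(one, path)
  b1 <- read_photons(path)
  expect_equal(length(b1), 1L)
  expect_equal(macrotime_s(b1), 0.5, tolerance = 1e-7)
  expect_equal(microtime_s(b1), 3e-9, tolerance = 1e-3)
  expect_equal(gate_labels(b1), "BBpar")
  unlink(path)
})

test_that("chunked read equals full read", {
  ps <- tiny_stream(2000, 5)
  path <- tempfile(fileext = ".tsv")
  write_photons(ps, path)
  full <- read_photons(path)
  c1 <- read_photons(path, nrows = 800)
  c2 <- read_photons(path, nrows = 800, skip = 800)
  c3 <- read_photons(path, skip = 1600)
  expect_identical(c(c1$macrotime, c2$macrotime, c3$macrotime), full$macrotime)
  expect_identical(c(c1$nanotime, c2$nanotime, c3$nanotime), full$nanotime)
  unlink(path)
})

test_that("missing mandatory fields are reported by name", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("# mfdburst-photons v1", "# sync_rate_hz=26670000",
               "macrotime\tnanotime", "1\t2"), path)
  expect_error(read_photons(path), "detector")
  writeLines(c("# mfdburst-photons v1", "macrotime\tnanotime\tdetector",
               "1\t2\tBpar"), path)
  expect_error(read_photons(path), "sync_rate_hz")
  unlink(path)
})
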