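# FRET computation, bleach detection, QC truncation, histogram frame
# selection.

test_that("FRET efficiency is I_A / (I_D + I_A) with clamping", {
  df <- tibble::tibble(
    molecule_id = "m1", frame = 1:4,
    donor = c(100, 0, 26, -50),
    acceptor = c(100, 50, 74, 120)
  )
  fr <- compute_fret(df, floor = 10)
  expect_equal(fr$efficiency, c(0.5, 1.0, 0.74, 1.0))
  expect_true(all(fr$valid))
})

test_that("E stays in [0,1] for arbitrary real inputs and low-signal frames are flagged", {
  vals <- with_seed(42, rnorm(400, 0, 500))
  df <- tibble::tibble(molecule_id = "m", frame = 1:200,
                       donor = vals[1:200], acceptor = vals[201:400])
  fr <- compute_fret(df, floor = 50)
  e <- fr$efficiency[!is.na(fr$efficiency)]
  expect_true(all(e >= 0 & e <= 1))
  expect_true(any(!fr$valid))
  expect_true(all(is.na(fr$efficiency[!fr$valid])))
})

test_that("injected bleaches are recovered within the detection window", {
  m <- folding_model(c(0.3, 0.74), 0.06, diag(2),
                     initial_distribution = c(0, 1))
  hits <- 0L
  for (r in 1:6) {
    b_true <- 100L + 20L * r
    phys <- photophysics(intensity_sd = 30, donor_bleach_prob = 0,
                         acceptor_bleach_prob = 0)
    tr <- emit_intensities(rep(2L, 400), m, phys, seed = r)
    # inject a clean acceptor bleach by hand at a known frame
    after <- tr$frame >= b_true
    tr$acceptor[after] <- phys$background +
      with_seed(r + 50, rnorm(sum(after), 0, 30))
    tr$donor[after] <- phys$total_intensity + phys$background +
      with_seed(r + 90, rnorm(sum(after), 0, 30))
    tr$molecule_id <- "m"
    ev <- detect_bleach(tr, window = 5, z_threshold = 4)
    if (nrow(ev) == 1 && ev$channel == "acceptor" &&
        abs(ev$frame - b_true) <= 5) {
      hits <- hits + 1L
    }
  }
  expect_equal(hits, 6L)
})

test_that("donor bleaches are attributed to the donor channel", {
  m <- folding_model(c(0.3, 0.74), 0.06, diag(2),
                     initial_distribution = c(0, 1))
  phys <- photophysics(intensity_sd = 20, donor_bleach_prob = 0,
                       acceptor_bleach_prob = 0)
  tr <- emit_intensities(rep(2L, 300), m, phys, seed = 3)
  after <- tr$frame >= 150
  tr$acceptor[after] <- phys$background + with_seed(1, rnorm(sum(after), 0, 20))
  tr$donor[after] <- phys$background + with_seed(2, rnorm(sum(after), 0, 20))
  tr$molecule_id <- "m"
  ev <- detect_bleach(tr, window = 5, z_threshold = 4)
  expect_gte(nrow(ev), 1)
  expect_true(any(ev$channel == "donor" & abs(ev$frame - 150) <= 5))
})

test_that("constant and short traces yield no bleach events", {
  df <- tibble::tibble(molecule_id = "m", frame = 1:100,
                       donor = rep(500, 100), acceptor = rep(500, 100))
  expect_equal(nrow(detect_bleach(df)), 0)
  short <- df[1:8, ]
  expect_equal(nrow(detect_bleach(short, window = 5)), 0)
})

test_that("folding transitions are not mistaken for bleaches", {
  # a sticky trace hopping between two real FRET levels keeps full signal
  m <- atrg3_model(self_prob = 0.9)
  sim <- simulate_traces(m, n_molecules = 10, n_frames = 300,
                         photophysics(donor_bleach_prob = 0,
                                      acceptor_bleach_prob = 0),
                         seed = 6)
  ev <- detect_bleach(sim)
  expect_equal(nrow(ev), 0)
})

test_that("truncation and QC rules apply per molecule", {
  fr <- tibble::tibble(
    molecule_id = rep(c("a", "b", "c"), each = 500),
    frame = rep(1:500, 3),
    efficiency = 0.5, valid = TRUE
  )
  ev <- tibble::tibble(
    molecule_id = c("a", "b", "c", "c"),
    frame = c(101L, 11L, 200L, 300L),
    channel = c("acceptor", "acceptor", "donor", "donor")
  )
  out <- truncate_and_filter(fr, ev, min_frames = 30)
  qc <- qc_report(out)
  expect_equal(qc$status[qc$molecule_id == "a"], "accepted")
  expect_equal(max(out$frame[out$molecule_id == "a"]), 100)
  expect_equal(qc$reason[qc$molecule_id == "b"], "too_short")
  expect_equal(qc$reason[qc$molecule_id == "c"], "multistep_bleach")
  expect_false(any(out$molecule_id %in% c("b", "c")))
})

test_that("histogram frame selection takes the earliest 30-50 frames", {
  fr <- tibble::tibble(
    molecule_id = rep(c("long", "mid", "short"), c(500, 37, 29)),
    frame = c(1:500, 1:37, 1:29),
    efficiency = 0.5, valid = TRUE
  )
  sel <- select_histogram_frames(fr)
  expect_equal(sum(sel$molecule_id == "long"), 50)
  expect_equal(max(sel$frame[sel$molecule_id == "long"]), 50)
  expect_equal(sum(sel$molecule_id == "mid"), 37)
  expect_false("short" %in% sel$molecule_id)
})

test_that("no molecule contributes more than 50 frames to a histogram", {
  sim <- simulate_traces(atrg3_model(), n_molecules = 20, n_frames = 200,
                         seed = 13)
  proc <- process_traces(sim)
  per_mol <- table(proc$histogram_frames$molecule_id)
  expect_true(all(per_mol <= 50))
  expect_true(all(per_mol >= 30))
})
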