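toy_seed <- function(n_protos = 1) {
  strand <- generate_toy_protofilament(3, n_residues = 3)
  strand <- strand[strand$chain == "A", ]
  purrr::map_dfr(seq_len(n_protos), function(i) {
    dplyr::mutate(strand, proto = paste0("P", i), y = y + (i - 1) * 12)
  })
}

test_that("helical replication preserves rigid-body geometry exactly", {
  seed <- toy_seed()
  one <- replicate_helix(seed, n_monomers = 1)
  expect_equal(one$atoms$x, seed$x)
  expect_equal(one$atoms$z, seed$z)
  fil <- replicate_helix(seed, n_monomers = 360, rise = 4.7, twist = 1)
  expect_equal(nrow(fil$atoms), 360 * nrow(seed))
  # intra-monomer pairwise distances identical to the seed (1e-6 A)
  pd <- function(df) as.vector(dist(cbind(df$x, df$y, df$z)))
  ref <- pd(seed)
  for (k in c(2, 180, 360)) {
    mk <- dplyr::filter(fil$atoms, monomer == k)
    expect_lt(max(abs(pd(mk) - ref)), 1e-6)
  }
  # consecutive monomers are separated axially by exactly the rise
  z_by_monomer <- dplyr::summarise(
    dplyr::group_by(fil$atoms, monomer), z = mean(z), .groups = "drop")
  expect_equal(diff(z_by_monomer$z), rep(4.7, 359), tolerance = 1e-9)
  # net rotation of the last monomer is 359 degrees about the axis
  a1 <- dplyr::filter(fil$atoms, monomer == 1)[1, ]
  a360 <- dplyr::filter(fil$atoms, monomer == 360)[1, ]
  ang <- function(x, y) atan2(y, x) * 180 / pi
  rot <- (ang(a360$x, a360$y) - ang(a1$x, a1$y)) %% 360
  expect_equal(rot, (-359) %% 360, tolerance = 1e-6)
})

test_that("axial length follows monomer count times rise", {
  seed <- toy_seed()
  expect_equal(axial_length(replicate_helix(seed, 1)), 0.47)
  expect_equal(axial_length(replicate_helix(seed, 360)), 169.2)
  expect_equal(axial_length(replicate_helix(seed, 100)), 47)
  expect_error(replicate_helix(seed, 10, rise = 0), "rise")
})

test_that("handedness flips the sense of rotation", {
  seed <- toy_seed()
  left <- replicate_helix(seed, 90, twist = 1, handedness = "left")
  right <- replicate_helix(seed, 90, twist = 1, handedness = "right")
  # signed in-plane rotation of an off-axis atom after 89 monomer steps
  pick <- function(m, k) dplyr::filter(m$atoms, monomer == k, elety == "CA",
                                       resno == 2)
  ang <- function(a) atan2(a$y, a$x) * 180 / pi
  d_left <- (ang(pick(left, 90)) - ang(pick(left, 1))) %% 360
  d_right <- (ang(pick(right, 90)) - ang(pick(right, 1))) %% 360
  expect_equal(d_left, 271, tolerance = 1e-6)  # -89 degrees, left-handed
  expect_equal(d_right, 89, tolerance = 1e-6)
})

test_that("isoform assignment validates lengths and keeps axial order", {
  seed <- toy_seed()
  fil <- replicate_helix(seed, 4)
  alt <- chain_from_string("4343")
  fil <- assign_isoforms(fil, list(P1 = alt))
  labels <- fil$atoms |>
    dplyr::distinct(monomer, isoform) |>
    dplyr::arrange(monomer)
  expect_identical(labels$isoform, c("4R", "3R", "4R", "3R"))
  expect_error(assign_isoforms(replicate_helix(seed, 5), list(P1 = alt)),
               "5 monomers")
  expect_error(assign_isoforms(replicate_helix(seed, 4), list(XX = alt)),
               "match")
})

test_that("mmCIF round trip preserves coordinates, metadata, and labels", {
  seed <- toy_seed(2)
  fil <- replicate_helix(seed, 25, rise = 4.7, twist = 1)
  p <- measured_probs()
  chains <- list(P1 = simulate_chain(p, 25, seed = 31),
                 P2 = simulate_chain(p, 25, seed = 32))
  fil <- assign_isoforms(fil, chains)
  tf <- withr::local_tempfile(fileext = ".cif")
  write_filament_cif(fil, tf)
  back <- read_filament_cif(tf)
  expect_equal(back$n_monomers, 25)
  expect_equal(back$rise, 4.7)
  expect_equal(back$twist, 1)
  expect_identical(back$handedness, "left")
  expect_lt(max(abs(back$atoms$x - fil$atoms$x)), 1e-4 + 1e-12)
  expect_lt(max(abs(back$atoms$z - fil$atoms$z)), 1e-4 + 1e-12)
  expect_identical(back$isoforms$P1, as.character(chains$P1))
  expect_identical(back$isoforms$P2, as.character(chains$P2))
  # empirical transition statistics survive the file round trip
  expect_equal(chain_stats(back$isoforms$P1)$f43, chain_stats(chains$P1)$f43)
  # sidecar labels match
  side <- jsonlite::read_json(paste0(tf, ".labels.json"), simplifyVector = TRUE)
  expect_identical(side$P1, as.character(chains$P1))
})

test_that("the PDB writer enforces the fixed-width atom limit", {
  seed <- toy_seed()
  big <- replicate_helix(seed, 7000) # 15 atoms x 7000 monomers > 99,999
  expect_error(write_filament_pdb(big, withr::local_tempfile(fileext = ".pdb")),
               "99,999")
  small <- replicate_helix(seed, 3)
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_filament_pdb(small, tf)
  expect_true(file.exists(tf))
  expect_equal(length(grep("^ATOM", readLines(tf))), nrow(small$atoms))
})
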