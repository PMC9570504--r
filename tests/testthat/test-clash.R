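test_that("PDB reading applies the altloc/water/hydrogen dialect rules", {
  atoms <- data.frame(
    atom = c("CA", "CB", "O", "OW"),
    resid = c("ALA", "ALA", "HOH", "HOH"),
    chain = "A", resno = c(1, 1, 90, 91),
    x = c(0, 1.5, 8, 9), y = 0, z = 0, stringsAsFactors = FALSE)
  p <- write_toy_pdb(atoms)
  s <- read_structure(p)
  expect_equal(nrow(s), 2)                      # waters skipped
  expect_equal(s$x, c(0, 1.5))
  expect_equal(s$element, c("C", "C"))

  # alternate locations: highest occupancy kept
  alt <- data.frame(
    atom = c("CA", "CA", "CB"), resid = "ALA", chain = "A", resno = 1,
    x = c(0, 3, 1), y = 0, z = 0, occ = c(0.3, 0.7, 1),
    altloc = c("A", "B", ""), stringsAsFactors = FALSE)
  s2 <- read_structure(write_toy_pdb(alt))
  expect_equal(nrow(s2), 2)
  expect_equal(s2$x[s2$atom == "CA"], 3)        # the 0.7-occupancy copy

  # errors: no ATOM records; truncated record names its line
  f1 <- tempfile(); writeLines(c("HEADER junk", "END"), f1)
  expect_error(read_structure(f1), "no ATOM")
  f2 <- tempfile()
  lines <- readLines(p)
  writeLines(c(lines[1], substr(lines[2], 1, 40)), f2)
  expect_error(read_structure(f2), "line 2")

  # unknown element: warning, scan still works with the default radius
  ph <- data.frame(atom = c("P1", "C1"), resid = "LIG", chain = "A",
                   resno = 1:2, x = c(0, 3), y = 0, z = 0,
                   stringsAsFactors = FALSE)
  expect_warning(s3 <- read_structure(write_toy_pdb(ph)), "P")
  expect_equal(nrow(s3), 2)
})

test_that("clash classification follows the van der Waals arithmetic", {
  # two carbons: radii sum 3.4 A
  two_c <- function(d) {
    atoms <- data.frame(atom = c("C1", "C2"), resid = "LIG", chain = "A",
                        resno = c(1, 2), x = c(0, d), y = 0, z = 0,
                        stringsAsFactors = FALSE)
    read_structure(write_toy_pdb(atoms))
  }
  r <- clash_scan(two_c(2.5), "A:1", "A:2", tolerance = 0.4)
  expect_equal(nrow(r), 1)
  expect_equal(r$classification, "clash")        # 2.5 < 3.4 - 0.4
  expect_equal(r$overlap, 3.4 - 2.5 - 0.4)

  r2 <- clash_scan(two_c(3.5), "A:1", "A:2", tolerance = 0.4)
  expect_equal(r2$classification, "contact")     # 3.0 <= 3.5 < 3.9

  r3 <- clash_scan(two_c(4.5), "A:1", "A:2", tolerance = 0.4)
  expect_equal(r3$classification, "none")

  # covalently bonded pairs are excluded
  r4 <- clash_scan(two_c(1.5), "A:1", "A:2")
  expect_equal(nrow(r4), 0)

  # identical single-residue selections: self pairs excluded, empty report
  one <- data.frame(atom = c("CA", "CB"), resid = "ALA", chain = "A",
                    resno = 1, x = c(0, 1.5), y = 0, z = 0,
                    stringsAsFactors = FALSE)
  s1 <- read_structure(write_toy_pdb(one))
  expect_equal(nrow(clash_scan(s1, "A:1", "A:1")), 0)

  expect_error(clash_scan(two_c(3), "A:7", "A:2"), "empty selection")
})

test_that("grid scan equals the brute-force all-pairs oracle exactly", {
  for (case in list(c(n = 60, seed = 1), c(n = 300, seed = 2),
                    c(n = 500, seed = 3))) {
    s <- read_structure(write_toy_pdb(random_toy_structure(case["n"],
                                                           case["seed"])))
    got <- clash_scan(s, "A:1-500", "B:1-500", tolerance = 0.4)
    want <- brute_force_clash(s, "A:1-500", "B:1-500", tolerance = 0.4)
    expect_equal(nrow(got), if (is.null(want)) 0 else nrow(want))
    if (!is.null(want)) {
      key_got <- paste(got$chain_a, got$resno_a, got$atom_a,
                       got$chain_b, got$resno_b, got$atom_b)
      key_want <- paste(s$chain[want$a], s$resno[want$a], s$atom[want$a],
                        s$chain[want$b], s$resno[want$b], s$atom[want$b])
      expect_setequal(key_got, key_want)
      ord <- match(key_want, key_got)
      expect_equal(got$distance[ord], want$distance, tolerance = 1e-12)
      expect_identical(got$classification[ord], want$classification)
    }
  }
})

test_that("clash report is selection-symmetric and tolerance-monotone", {
  s <- read_structure(write_toy_pdb(random_toy_structure(150, seed = 4)))
  ab <- clash_scan(s, "A:1-150", "B:1-150")
  ba <- clash_scan(s, "B:1-150", "A:1-150")
  expect_equal(ab, ba)

  tols <- c(0, 0.2, 0.4, 0.8, 1.5)
  counts <- vapply(tols, function(tol)
    sum(clash_scan(s, "A:1-150", "B:1-150", tolerance = tol)$classification
        == "clash"), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("interface profile reports contacts, misses and rigid invariance", {
  # two 'helices': NT residue 14 close to TM2 residue 89 (3.6 A), the rest
  # far; residues 1-9 of the NT left unmodeled
  nt <- data.frame(atom = "CB", resid = "ALA", chain = "A", resno = 10:17,
                   x = 0, y = seq(0, 21, by = 3), z = 0,
                   stringsAsFactors = FALSE)
  tm2 <- data.frame(atom = "CB", resid = "LEU", chain = "A", resno = 85:95,
                    x = 30, y = seq(0, 30, by = 3), z = 0,
                    stringsAsFactors = FALSE)
  # put residue 89 exactly 3.6 A from residue 14
  y14 <- nt$y[nt$resno == 14]
  tm2$x[tm2$resno == 89] <- 3.6
  tm2$y[tm2$resno == 89] <- y14
  s <- read_structure(write_toy_pdb(rbind(nt, tm2)))
  prof <- interface_profile(s, nt_range = 4:17, tm2_range = 85:95)

  hit <- prof[prof$nt_res == 14 & prof$tm2_res == 89 & !prof$missing, ]
  expect_equal(hit$min_dist, 3.6, tolerance = 1e-6)
  expect_equal(hit$classification, "contact")     # 3.4 <= 3.6 < 3.9

  # unmodeled NT residues are flagged missing, not fatal
  expect_true(all(prof$missing[prof$nt_res <= 9]))

  # rigid translation leaves the report unchanged
  shifted <- rbind(nt, tm2)
  shifted$x <- shifted$x + 10; shifted$y <- shifted$y + 10
  shifted$z <- shifted$z + 10
  s2 <- read_structure(write_toy_pdb(shifted))
  prof2 <- interface_profile(s2, nt_range = 4:17, tm2_range = 85:95)
  expect_equal(prof2$min_dist, prof$min_dist, tolerance = 1e-6)
  expect_identical(prof2$classification, prof$classification)
})

test_that("selection parser handles ranges and rejects junk", {
  sel <- parse_selection(c("A:4-17", "B:90"))
  expect_equal(nrow(sel), 15)
  expect_setequal(unique(sel$chain), c("A", "B"))
  expect_error(parse_selection("A4-17"), "cannot parse")
})
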