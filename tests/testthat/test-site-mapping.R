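test_that("residue labels parse into number and side-chain tag", {
  p <- parseResidueLabel(c("R96", "Trp119", "W119NE1", "???"))
  expect_identical(p$number, c(96L, 119L, 119L, NA_integer_))
  expect_identical(p$tag, c("", "", "NE1", ""))
})

test_that("contiguous significant residues group into the three patches", {
  labs <- paste0("X", c(96:100, 117:120, 135:137))
  pr <- findPatches(cspStub(labs))
  expect_identical(nrow(patches(pr)), 3L)
  expect_identical(patches(pr)$start, c(96L, 117L, 135L))
  expect_identical(patches(pr)$end, c(100L, 120L, 137L))
  expect_identical(lengths(pr@members), c(5L, 4L, 3L))
  expect_length(pr@singletons, 0)
})

test_that("patch grouping honours max_gap and ordering invariance", {
  pr2 <- findPatches(cspStub(c("A10", "A12")), maxGap = 2)
  expect_identical(patches(pr2)$start, 10L)
  expect_identical(patches(pr2)$end, 12L)
  pr1 <- findPatches(cspStub(c("A10", "A12")), maxGap = 1)
  expect_identical(nrow(patches(pr1)), 0L)
  expect_setequal(pr1@singletons, c("A10", "A12"))
  # input ordering must not matter
  labs <- paste0("X", c(137, 96, 119, 135, 100, 117, 99, 136, 118, 98, 97, 120))
  prS <- findPatches(cspStub(labs))
  expect_identical(patches(prS)$start, c(96L, 117L, 135L))
  expect_identical(patches(prS)$end, c(100L, 120L, 137L))
})

test_that("empty sets, side chains and unparseable labels are routed correctly", {
  prE <- findPatches(cspStub(c("A1", "A2"), significant = c(FALSE, FALSE)))
  expect_identical(nrow(patches(prE)), 0L)
  expect_length(pr <- prE@singletons, 0)

  pr <- findPatches(cspStub(c("W119NE1", "W119", "W120", "G117", "D118")))
  expect_identical(pr@sideChainHits, "W119NE1")
  expect_identical(patches(pr)$start, 117L)  # side chain not in backbone run
  expect_identical(patches(pr)$end, 120L)

  expect_warning(prB <- findPatches(cspStub(c("96abc", "A10"))),
                 "unparseable")
  expect_true("96abc" %in% prB@singletons)
})

test_that("structure mapping writes ddMax into the B column and nothing else", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  out <- withr::local_tempfile(fileext = ".pdb")
  writeTinyPdb(pdb, resnos = c(96, 97, 98))
  csp <- cspStub(c("R96"), ddMax = 0.5)
  expect_warning(writeStructureMap(pdb, csp, out), NA)
  inL <- readLines(pdb); outL <- readLines(out)
  expect_identical(length(inL), length(outL))
  atom <- startsWith(inL, "ATOM")
  expect_identical(inL[!atom], outL[!atom])
  # only columns 61-66 may differ
  expect_identical(substr(inL[atom], 1, 60), substr(outL[atom], 1, 60))
  expect_identical(substr(inL[atom], 67, 80), substr(outL[atom], 67, 80))
  b <- trimws(substr(outL[atom], 61, 66))
  res <- as.integer(trimws(substr(outL[atom], 23, 26)))
  expect_true(all(b[res == 96] == "50.00"))
  expect_true(all(b[res != 96] == "-1.00"))
})

test_that("structure mapping cross-checks against bio3d and flags misses", {
  skip_if_not_installed("bio3d")
  pdb <- withr::local_tempfile(fileext = ".pdb")
  out <- withr::local_tempfile(fileext = ".pdb")
  writeTinyPdb(pdb, resnos = c(96, 97, 98))
  csp <- cspStub(c("R96", "T97", "K140"), ddMax = c(0.5, 0.12, 0.3))
  expect_warning(writeStructureMap(pdb, csp, out), "K140")
  b3 <- bio3d::read.pdb(out)
  ca <- b3$atom[b3$atom$elety == "CA", ]
  expect_equal(ca$b[match(c(96, 97, 98), ca$resno)],
               c(50, 12, -1), tolerance = 1e-6)
})

test_that("side-chain values combine with backbone by maximum", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  out <- withr::local_tempfile(fileext = ".pdb")
  writeTinyPdb(pdb, resnos = c(119), resns = c("TRP"))
  csp <- cspStub(c("W119", "W119NE1"), ddMax = c(0.1, 0.3))
  writeStructureMap(pdb, csp, out)
  atom <- grep("^ATOM", readLines(out), value = TRUE)
  expect_true(all(trimws(substr(atom, 61, 66)) == "30.00"))
})

test_that("empty tables give sentinels and malformed PDB lines error", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  out <- withr::local_tempfile(fileext = ".pdb")
  writeTinyPdb(pdb)
  writeStructureMap(pdb, cspStub(character(0), significant = logical(0),
                                 ddMax = numeric(0), overlap = logical(0)),
                    out)
  atom <- grep("^ATOM", readLines(out), value = TRUE)
  expect_true(all(trimws(substr(atom, 61, 66)) == "-1.00"))

  writeLines(c("ATOM      1  N   ARG A  96"), pdb)
  expect_error(writeStructureMap(pdb, cspStub("R96"), out), "line 1")
})
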