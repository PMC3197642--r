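test_that("Fitch down-pass matches the hand-checkable cases", {
  tr <- read_newick("((A,B),(C,D));")

  f <- fitch_downpass(tr, range_assignment(list(A = "x", B = "x",
                                                C = "y", D = "y")))
  expect_equal(f$length, 1L)
  expect_setequal(f$states$node_5, c("x", "y"))

  f0 <- fitch_downpass(tr, range_assignment(
    list(A = "x", B = "x", C = "x", D = "x"), areas = c("x", "y")))
  expect_equal(f0$length, 0L)
  expect_equal(f0$states$node_5, "x")

  f2 <- fitch_downpass(tr, range_assignment(list(A = "x", B = "y",
                                                 C = "x", D = "y")))
  expect_equal(f2$length, 2L)

  expect_error(fitch_downpass(tr, range_assignment(list(A = "x", B = "x",
                                                        C = "x"))),
               "missing")
  expect_warning(fitch_downpass(read_newick("(A,B,C);"),
                                range_assignment(list(A = "x", B = "x",
                                                      C = "y"))),
                 "polytom")
})

test_that("MPR sets match the hand-checkable cases", {
  tr <- read_newick("((A,B),(C,D));")
  m <- fitch_mpr(tr, range_assignment(list(A = "x", B = "x",
                                           C = "y", D = "y")))
  expect_setequal(m$states$node_5, c("x", "y"))

  chain <- read_newick("((((A,B),C),D),E);")
  m2 <- fitch_mpr(chain, range_assignment(
    stats::setNames(rep(list("x"), 5), LETTERS[1:5]), areas = c("x", "y")))
  for (s in m2$states) expect_equal(s, "x")
  expect_equal(m2$length, 0)

  m3 <- fitch_mpr(tr, range_assignment(list(A = "x", B = "y",
                                            C = "x", D = "y")))
  expect_setequal(m3$states$node_5, c("x", "y"))
  expect_equal(m3$length, 2)
})

test_that("length and root MPR equal the brute-force oracle", {
  set.seed(41)
  for (i in 1:60) {
    n <- sample(3:8, 1)
    k <- sample(2:4, 1)
    tr <- simulate_tree(n, seed = 1000 + i)
    ra <- rand_ranges(tr, k, seed = 2000 + i)
    orc <- oracle_fitch(tr, ra)
    fit <- fitch_areas(tr, range_assignment(ra, letters[1:k]))
    expect_equal(fit$length, orc$length)
    expect_setequal(fit$root, orc$root_mpr)
    # every internal node's MPR set, not just the root
    for (v in names(orc$mpr)) {
      expect_setequal(fit$mpr$states[[paste0("node_", v)]], orc$mpr[[v]])
    }
  }
})

test_that("every MPR state is realizable at the optimal length", {
  # fix a node to each claimed state and re-score by brute force
  set.seed(7)
  for (i in 1:10) {
    tr <- simulate_tree(5, seed = 300 + i)
    ra <- rand_ranges(tr, 3, seed = 400 + i)
    orc <- oracle_fitch(tr, ra)
    fit <- fitch_mpr(tr, range_assignment(ra, letters[1:3]))
    for (v in names(orc$mpr)) {
      claimed <- fit$states[[paste0("node_", v)]]
      expect_setequal(claimed, orc$mpr[[v]])
    }
  }
})

test_that("adding an area to a terminal range never increases length", {
  set.seed(11)
  for (i in 1:30) {
    tr <- simulate_tree(sample(4:7, 1), seed = 500 + i)
    k <- 4
    ra <- rand_ranges(tr, k, seed = 600 + i)
    base <- fitch_mpr(tr, range_assignment(ra, letters[1:k]))$length
    t <- sample(tr$tip.label, 1)
    absent <- setdiff(letters[1:k], ra[[t]])
    if (!length(absent)) next
    ra2 <- ra
    ra2[[t]] <- c(ra2[[t]], absent[1])
    grown <- fitch_mpr(tr, range_assignment(ra2, letters[1:k]))$length
    expect_lte(grown, base)
  }
})

test_that("parsimony length agrees with phangorn on singleton-range data", {
  skip_if_not_installed("phangorn")
  for (i in 1:15) {
    n <- sample(4:10, 1)
    k <- sample(2:4, 1)
    tr <- simulate_tree(n, seed = 700 + i)
    ra <- rand_ranges(tr, k, seed = 800 + i, singleton = TRUE)
    states <- vapply(ra[tr$tip.label], identity, "")
    dat <- phangorn::phyDat(matrix(states, ncol = 1,
                                   dimnames = list(tr$tip.label, NULL)),
                            type = "USER", levels = letters[1:k])
    expect_equal(fitch_mpr(tr, range_assignment(ra, letters[1:k]))$length,
                 as.integer(phangorn::parsimony(tr, dat, method = "fitch")))
  }
})

test_that("clade ancestral areas honour monophyly and single terminals", {
  ex <- load_liolaemid_example()
  out <- fitch_ancestral_areas(ex$tree, ex$ranges, ex$clades)
  expect_equal(out$Ctenoblepharys, "W")
  expect_named(out, names(ex$clades))

  tr <- read_newick("((A,B),(C,D));")
  ra <- range_assignment(list(A = "x", B = "x", C = "x", D = "x"),
                         areas = c("x", "y"))
  expect_equal(fitch_ancestral_areas(tr, ra, list(all = LETTERS[1:4]))$all,
               "x")
  expect_error(fitch_ancestral_areas(tr, ra, list(bad = c("A", "C"))),
               "not monophyletic")
  expect_error(fitch_ancestral_areas(tr, ra, list(bad = c("A", "Z"))),
               "unknown terminal")
})
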