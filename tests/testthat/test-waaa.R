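test_that("directional gain and loss weights match the forced cases", {
  tr <- read_newick("((A,B),(C,D));")
  all_present <- c(A = TRUE, B = TRUE, C = TRUE, D = TRUE)
  # universal area: one gain on the virtual origin edge, never lost
  expect_equal(count_gains(tr, all_present), 1)
  expect_equal(count_losses(tr, all_present), 0)

  # single presence at a tip whose entering edge is level 3
  one_tip <- c(A = TRUE, B = FALSE, C = FALSE, D = FALSE)
  expect_equal(count_gains(tr, one_tip), 1 / 3)

  # presence only in the left child of the root (a terminal): one loss on
  # the right root-child edge, level 2
  tr2 <- read_newick("(A,(C,D));")
  expect_equal(count_losses(tr2, c(A = TRUE, C = FALSE, D = FALSE)), 1 / 2)

  expect_error(count_gains(tr, c(A = FALSE, B = FALSE, C = FALSE, D = FALSE)),
               "present in no terminal")
})

test_that("gain and loss weights equal the exhaustive placement oracle", {
  set.seed(5)
  for (i in 1:60) {
    n <- sample(3:7, 1)
    tr <- simulate_tree(n, seed = 3000 + i)
    pres <- ancarea:::with_seed(4000 + i, {
      p <- stats::runif(n) < 0.5
      if (!any(p)) p[sample.int(n, 1)] <- TRUE
      stats::setNames(p, tr$tip.label)
    })
    expect_equal(count_gains(tr, pres), oracle_gains(tr, pres))
    expect_equal(count_losses(tr, pres), oracle_losses(tr, pres))
  }
})

test_that("probability index ranks, rescales and flags never-lost areas", {
  tr <- read_newick("((A,B),(C,D));")
  ra <- range_assignment(list(A = c("x", "y"), B = "x", C = "x", D = "x"))
  pit <- probability_index(tr, ra)
  expect_s3_class(pit, "pi_table")
  expect_equal(pit$area[1], "x")
  expect_true(pit$never_lost[1])
  expect_equal(pit$PI[1], Inf)
  expect_equal(pit$rescaled_PI[1], 1)
  expect_equal(pit$rank, seq_len(nrow(pit)))

  # mirror-image presence patterns on a symmetric tree have equal PI
  ra2 <- range_assignment(list(A = "x", B = "x", C = "y", D = "y"))
  pit2 <- probability_index(tr, ra2)
  expect_equal(pit2$PI[1], pit2$PI[2])
  expect_equal(pit2$GW[1], pit2$GW[2])
})

test_that("PI is invariant to relabeling and child reordering", {
  tr <- read_newick("((A,B),(C,D));")
  ra <- range_assignment(list(A = c("x", "y"), B = "y", C = "x",
                              D = c("x", "z")))
  pit <- probability_index(tr, ra)

  swapped <- read_newick("((C,D),(B,A));")
  pit_sw <- probability_index(swapped, ra)
  expect_equal(as.data.frame(pit), as.data.frame(pit_sw))

  relab <- read_newick("((P,Q),(R,S));")
  ra_rl <- range_assignment(list(P = c("x", "y"), Q = "y", R = "x",
                                 S = c("x", "z")))
  pit_rl <- probability_index(relab, ra_rl)
  expect_equal(pit$PI, pit_rl$PI)
})

test_that("the universal-presence area always ranks first", {
  set.seed(9)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    tr <- simulate_tree(n, seed = 5000 + i)
    ra <- rand_ranges(tr, 3, seed = 6000 + i)
    ra <- lapply(ra, function(r) unique(c(r, "u")))  # area u everywhere
    pit <- probability_index(tr, range_assignment(ra))
    u_rank <- pit$rank[pit$area == "u"]
    expect_true(pit$never_lost[pit$area == "u"])
    expect_equal(pit$rescaled_PI[pit$area == "u"], 1)
    # only other never-lost areas may tie ahead of the universal area
    expect_true(all(pit$never_lost[pit$rank < u_rank]))
  }
})

test_that("the ancestral set honours the threshold and keeps the top area", {
  pit <- structure(data.frame(area = c("A", "B", "C"),
                              GW = c(1, .5, .2), LW = c(0, .5, 1),
                              PI = c(Inf, 1, .2),
                              rescaled_PI = c(1, 0.6, 0.1),
                              never_lost = c(TRUE, FALSE, FALSE),
                              rank = 1:3),
                   class = c("pi_table", "data.frame"))
  expect_equal(waaa_ancestral_set(pit, 0.5), c("A", "B"))
  expect_equal(waaa_ancestral_set(pit, 1.0), "A")
  tied <- pit
  tied$rescaled_PI <- c(1, 1, 1)
  expect_equal(waaa_ancestral_set(tied, 1.0), c("A", "B", "C"))
})

test_that("PI restricted to a clade ignores terminals outside it", {
  tr <- read_newick("(((A,B),(C,D)),(E,F));")
  ra <- range_assignment(list(A = "x", B = c("x", "y"), C = "y", D = "x",
                              E = "z", F = "z"))
  sub <- ape::keep.tip(tr, LETTERS[1:4])
  direct <- probability_index(sub, range_assignment(ra[LETTERS[1:4]],
                                                    attr(ra, "areas")))
  via_clade <- ancarea:::waaa_clade(tr, ra, LETTERS[1:4])
  expect_setequal(via_clade, waaa_ancestral_set(direct))
})

test_that("an isolated extra presence adds exactly its own edge weight", {
  # growing the pattern by a terminal that forms its own maximal gain clade
  # (its parent stays incompletely present) adds 1/level(tip) to GW
  set.seed(13)
  checked <- 0L
  for (i in 1:40) {
    n <- sample(4:8, 1)
    tr <- simulate_tree(n, seed = 7000 + i)
    depth <- tree_depths(tr)
    pres <- ancarea:::with_seed(7100 + i, {
      p <- stats::runif(n) < 0.4
      if (!any(p)) p[sample.int(n, 1)] <- TRUE
      stats::setNames(p, tr$tip.label)
    })
    off <- names(pres)[!pres]
    if (!length(off)) next
    tip_lab <- off[1]
    tip <- match(tip_lab, tr$tip.label)
    bigger <- pres
    bigger[tip_lab] <- TRUE
    # skip if the addition completes the tip's parent clade
    parent <- tr$edge[tr$edge[, 2] == tip, 1]
    sibs <- setdiff(tips_in_subtree(tr, parent), tip_lab)
    if (all(bigger[sibs])) next
    expect_equal(count_gains(tr, bigger),
                 count_gains(tr, pres) + 1 / (depth[tip] + 1))
    checked <- checked + 1L
  }
  expect_gte(checked, 10L)
})
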