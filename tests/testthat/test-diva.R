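test_that("split costs follow the vicariance/dispersal/extinction scheme", {
  expect_equal(split_cost(c("a", "b"), "a", "b"), 0L)
  expect_equal(split_cost("a", "a", c("a", "b")), 1L)
  expect_equal(split_cost("a", "b", "a"), 2L)
  expect_equal(split_cost(c("a", "b", "c"), c("a", "b"), "c"), 0L)
  expect_error(split_cost(character(0), "a", "a"), "non-empty")

  # agreement with the enumeration oracle on random triples
  set.seed(3)
  for (i in 1:50) {
    areas <- letters[1:4]
    pick <- function() sort(sample(areas, sample(1:4, 1)))
    a <- pick(); l <- pick(); r <- pick()
    expect_equal(split_cost(a, l, r), oracle_split_cost(a, l, r))
  }
})

test_that("the worked three-terminal example is solved exactly", {
  tr <- read_newick("((t1,t2),t3);")
  fit <- diva(tr, range_assignment(list(t1 = "a", t2 = "b", t3 = "a")))
  expect_equal(fit$cost, 1)
  expect_true(set_list_equal(fit$root_optima, list("a", c("a", "b"))))
  expect_equal(fit$n_optimal, 2)
  expect_false(fit$truncated)
  roots <- lapply(fit$reconstructions, function(r) r$nodes$node_4)
  expect_true(set_list_equal(roots, list("a", c("a", "b"))))
  inner <- lapply(fit$reconstructions, function(r) r$nodes$node_5)
  expect_true(all(vapply(inner, setequal, TRUE, y = c("a", "b"))))

  # hold = 1 truncates but the exact count is still reported
  held <- diva(tr, range_assignment(list(t1 = "a", t2 = "b", t3 = "a")),
               hold = 1)
  expect_equal(length(held$reconstructions), 1L)
  expect_true(held$truncated)
  expect_equal(held$n_optimal, 2)
})

test_that("pure-vicariance terminals cost 0 with the union as root", {
  tr <- read_newick("((t1,t2),t3);")
  fit <- diva(tr, range_assignment(list(t1 = "a", t2 = "b", t3 = "c")))
  expect_equal(fit$cost, 0)
  expect_true(set_list_equal(fit$root_optima, list(c("a", "b", "c"))))
  expect_equal(fit$n_optimal, 1)

  cherry <- diva(read_newick("(t1,t2);"),
                 range_assignment(list(t1 = "a", t2 = "a"), areas = "a"))
  expect_equal(cherry$cost, 0)
  expect_true(set_list_equal(cherry$root_optima, list("a")))
})

test_that("DIVA preconditions are enforced", {
  poly <- read_newick("(t1,t2,t3);")
  ra <- range_assignment(list(t1 = "a", t2 = "a", t3 = "a"), areas = "a")
  expect_error(diva(poly, ra), "binary")
  tr <- read_newick("((t1,t2),t3);")
  ra2 <- range_assignment(list(t1 = c("a", "b"), t2 = "a", t3 = "a"))
  expect_error(diva(tr, ra2, maxareas = 1), "maxareas")
  expect_error(diva(tr, ra2, weight = 2), "neutral")
  expect_error(diva(tr, ra2, age = 0.5), "neutral")
  expect_error(diva(tr, ra2, hold = 0), "hold")
})

test_that("DP cost and optima equal exhaustive brute force", {
  set.seed(17)
  for (i in 1:60) {
    n <- sample(3:6, 1)
    k <- sample(2:4, 1)
    tr <- simulate_tree(n, seed = 8000 + i)
    ra <- rand_ranges(tr, k, seed = 9000 + i)
    orc <- oracle_diva(tr, ra)
    fit <- diva(tr, range_assignment(ra, letters[1:k]))
    expect_equal(fit$cost, orc$cost)
    expect_true(set_list_equal(fit$root_optima, orc$root_optima))
    # per-node optimal subset families match too
    for (v in names(orc$node_optima)) {
      expect_true(set_list_equal(fit$node_optima[[paste0("node_", v)]],
                                 orc$node_optima[[v]]))
    }
  }
})

test_that("every enumerated reconstruction re-scores to the minimal cost", {
  set.seed(19)
  for (i in 1:15) {
    n <- sample(3:6, 1)
    k <- sample(2:4, 1)
    tr <- simulate_tree(n, seed = 8500 + i)
    ra <- rand_ranges(tr, k, seed = 9500 + i)
    fit <- diva(tr, range_assignment(ra, letters[1:k]))
    expect_equal(length(fit$reconstructions),
                 min(fit$n_optimal, fit$hold))
    for (rec in fit$reconstructions) {
      expect_equal(ancarea:::diva_rescore(tr, rec$nodes), fit$cost)
    }
    # reconstructions are distinct
    keys <- vapply(fit$reconstructions, function(r) {
      paste(vapply(r$nodes, function(s) paste(sort(s), collapse = ""), ""),
            collapse = "|")
    }, "")
    expect_equal(anyDuplicated(keys), 0L)
  }
})

test_that("minimal cost is non-increasing as maxareas grows", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(3:6, 1)
    k <- 4
    tr <- simulate_tree(n, seed = 8800 + i)
    ra <- rand_ranges(tr, k, seed = 9800 + i)
    mmin <- max(vapply(ra, length, 1L))
    costs <- vapply(mmin:k, function(m) {
      diva(tr, range_assignment(ra, letters[1:k]), maxareas = m)$cost
    }, 0)
    expect_true(all(diff(costs) <= 0))
    # the unconstrained fit equals maxareas = k
    expect_equal(costs[length(costs)],
                 diva(tr, range_assignment(ra, letters[1:k]))$cost)
  }
})

test_that("an inactive maxareas constraint leaves the answer unchanged", {
  tr <- read_newick("((t1,t2),t3);")
  ra <- range_assignment(list(t1 = "a", t2 = "b", t3 = "a"))
  free <- diva(tr, ra)
  capped <- diva(tr, ra, maxareas = 2)
  expect_equal(capped$cost, free$cost)
  expect_true(set_list_equal(capped$root_optima, free$root_optima))
})

test_that("a basal outgroup in a novel area enlarges the root union", {
  set.seed(29)
  for (i in 1:15) {
    n <- sample(3:6, 1)
    k <- sample(2:4, 1)
    tr <- simulate_tree(n, seed = 8600 + i)
    ra <- rand_ranges(tr, k, seed = 9600 + i)
    base <- diva(tr, range_assignment(ra, letters[1:k]))
    base_union <- diva_ancestral_area(base)

    nwk <- sub(";$", "", write_newick(tr))
    tr2 <- read_newick(paste0("(out,", nwk, ");"))
    ra2 <- c(ra, list(out = "z"))
    grown <- diva(tr2, range_assignment(ra2, c(letters[1:k], "z")))
    grown_union <- diva_ancestral_area(grown)
    expect_true(all(base_union %in% grown_union))
    expect_true("z" %in% grown_union)
  }
})

test_that("union and per-reconstruction ancestral modes agree", {
  tr <- read_newick("((t1,t2),t3);")
  fit <- diva(tr, range_assignment(list(t1 = "a", t2 = "b", t3 = "a")))
  expect_equal(diva_ancestral_area(fit, "union"), c("a", "b"))
  per <- diva_ancestral_area(fit, "per-reconstruction")
  expect_true(set_list_equal(per, list("a", c("a", "b"))))
})
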