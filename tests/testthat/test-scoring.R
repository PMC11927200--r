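test_that("sequentiality counts trend-consistent transitions out of 100", {
  tab <- load_default_indices()
  mw <- tab[["FASG760101"]]
  # strictly increasing molecular weight, positive slope -> perfect score
  up <- toy_trajectory(c("G", "A", "V", "L", "F"))
  expect_equal(sequentiality(up, mw, slope = 1), 100)
  # 4 transitions, 3 consistent with a rising trend:
  # G(75)->A(89)->V(117)->S(105)->F(165): one drop
  mixed <- toy_trajectory(c("G", "A", "V", "S", "F"))
  expect_equal(sequentiality(mixed, mw, slope = 1), 75)
  # every transition against the trend
  down <- toy_trajectory(c("F", "L", "V", "A", "G"))
  expect_equal(sequentiality(down, mw, slope = 1), 0)
  expect_equal(sequentiality(down, mw, slope = -1), 100)
  expect_error(sequentiality(toy_trajectory(rep("A", 3L)), mw, 1), "no transitions")
})

test_that("sequentiality is invariant under strictly increasing scale transforms", {
  tab <- load_default_indices()
  mw <- tab[["FASG760101"]]
  mono <- mw; mono$values <- exp(mw$values / 80)   # strictly increasing map
  set.seed(17)
  for (i in 1:25) {
    res <- sample(c("G", "A", "S", "V", "L", "F", "W"), sample(4:9, 1L),
                  replace = TRUE)
    tr <- toy_trajectory(res)
    if (tr$n_transitions < 1L) next
    for (slope in c(-1, 1)) {
      expect_equal(sequentiality(tr, mono, slope), sequentiality(tr, mw, slope))
    }
  }
})

test_that("fluctuation divides distinct residues by group count", {
  expect_equal(fluctuation(toy_trajectory(c("A", "A", "L", "L"))), 1.0)
  expect_equal(fluctuation(toy_trajectory(c("A", "L", "A", "L"))), 0.5)
  expect_equal(fluctuation(toy_trajectory(rep("W", 4L))), 1.0)
  degenerate <- structure(list(site = 0L, residues = character(0),
                               positions = numeric(0),
                               groups = data.frame(residue = character(0),
                                                   first = integer(0),
                                                   last = integer(0)),
                               n_transitions = 0L),
                          class = "trajectory")
  expect_error(fluctuation(degenerate), "empty")
})

test_that("break-trend flags a final transition that opposes the trend", {
  tab <- load_default_indices()
  mw <- tab[["FASG760101"]]
  up <- toy_trajectory(c("G", "A", "V", "L"))
  expect_false(break_trend(up, mw, slope = 1))
  final_drop <- toy_trajectory(c("G", "A", "V", "L", "S"))
  expect_true(break_trend(final_drop, mw, slope = 1))
  expect_false(break_trend(final_drop, mw, slope = -1))
  # I and L share a molecular weight: zero change is consistent
  tie <- toy_trajectory(c("G", "A", "I", "L"))
  expect_false(break_trend(tie, mw, slope = 1))
  # penultimate reading inspects the transition before the last
  pen <- toy_trajectory(c("G", "V", "A", "L"))   # drop at penultimate, rise at last
  expect_false(break_trend(pen, mw, slope = 1, mode = "last"))
  expect_true(break_trend(pen, mw, slope = 1, mode = "penultimate"))
  expect_warning(flag <- break_trend(toy_trajectory(c("A", "L")), mw, 1),
                 "fewer than two")
  expect_false(flag)
})

test_that("ranking is a stable total order on (break, sequentiality, fluctuation)", {
  base <- data.frame(position = c(4L, 2L, 9L, 2L, 7L),
                     accession = c("FASG760101", "ZIMJ680103", "BHAR880101",
                                   "FASG760101", "WOLR790101"),
                     sequentiality = c(100, 100, 80, 100, 80),
                     fluctuation = c(1.0, 0.5, 0.9, 1.0, 0.9),
                     break_trend = c(FALSE, FALSE, FALSE, TRUE, FALSE),
                     stringsAsFactors = FALSE)
  r <- rank_predictions(base)
  # high fluctuation beats low at equal sequentiality; breaks rank last
  expect_identical(r$position, c(4L, 2L, 7L, 9L, 2L))
  expect_true(all(which(r$break_trend) > max(which(!r$break_trend))))
  # permutation invariance (stability of the total order)
  set.seed(29)
  for (i in 1:10) {
    perm <- base[sample(nrow(base)), ]
    expect_identical(rank_predictions(perm)[, -1L], r[, -1L])
  }
  # ties resolved by position then accession, deterministically
  ties <- data.frame(position = c(5L, 3L, 3L),
                     accession = c("AAA", "BBB", "AAA"),
                     sequentiality = 90, fluctuation = 1,
                     break_trend = FALSE, stringsAsFactors = FALSE)
  rt <- rank_predictions(ties)
  expect_identical(rt$position, c(3L, 3L, 5L))
  expect_identical(rt$accession[1:2], c("AAA", "BBB"))
})

test_that("aggregation across trees averages scores per (site, mutation, index)", {
  row <- function(tree, seqn) {
    data.frame(tree_id = tree, site = 2L, position = 3L, wild_type = "E",
               predicted = "K", accession = "FASG760101", category = "Size",
               slope = 10, predicted_value = 160, sequentiality = seqn,
               fluctuation = 1, break_trend = FALSE, stringsAsFactors = FALSE)
  }
  agg <- aggregate_across_trees(rbind(row("t1", 100), row("t2", 80), row("t3", 90)))
  expect_identical(nrow(agg), 1L)
  expect_equal(agg$sequentiality, 90)
  expect_identical(agg$n_trees, 3L)
  single <- aggregate_across_trees(row("t1", 77))
  expect_equal(single$sequentiality, 77)
  expect_identical(single$n_trees, 1L)
  # wild-type conflict at one position across trees is a coordinate bug
  bad <- rbind(row("t1", 100), transform(row("t2", 90), wild_type = "D"))
  expect_error(aggregate_across_trees(bad), "differs across trees")
})

test_that("merged tuple count equals a brute-force group-by", {
  set.seed(41)
  wt_of <- c(`1` = "A", `2` = "E", `3` = "K", `4` = "L")
  n <- 80L
  pos <- sample(1:4, n, replace = TRUE)
  df <- data.frame(tree_id = sample(paste0("t", 1:5), n, replace = TRUE),
                   site = pos, position = pos,
                   wild_type = unname(wt_of[as.character(pos)]),
                   predicted = sample(c("V", "W", "Y"), n, replace = TRUE),
                   accession = sample(c("FASG760101", "ZIMJ680104"), n, TRUE),
                   category = "Size", slope = rnorm(n), predicted_value = 0,
                   sequentiality = runif(n, 0, 100), fluctuation = runif(n),
                   break_trend = sample(c(TRUE, FALSE), n, TRUE),
                   stringsAsFactors = FALSE)
  agg <- aggregate_across_trees(df)
  ref <- unique(df[, c("position", "wild_type", "predicted", "accession")])
  expect_identical(nrow(agg), nrow(ref))
  one <- df[df$position == df$position[1L] & df$predicted == df$predicted[1L] &
              df$accession == df$accession[1L], ]
  hit <- agg[agg$position == df$position[1L] & agg$predicted == df$predicted[1L] &
               agg$accession == df$accession[1L], ]
  expect_equal(hit$sequentiality, sum(one$sequentiality) / nrow(one))
})
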