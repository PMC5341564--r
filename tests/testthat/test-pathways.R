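test_that("GMT parsing handles descriptions, dedup and errors", {
  p <- write_lines_tmp(c("P1\tdesc\tA\tB", "P2\td\tA\tA\tB"), ".gmt")
  coll <- read_gmt(p)
  expect_length(coll, 2)
  expect_equal(coll[["P1"]], c("A", "B"))
  expect_equal(coll[["P2"]], c("A", "B"))  # within-set duplicate dropped
  expect_error(read_gmt(write_lines_tmp(c("P1\td\tA", "P1\td\tB"), ".gmt")),
               "duplicate")
  expect_error(read_gmt(write_lines_tmp("P1\tdesc", ".gmt")), "line 1")
})

test_that("pathway collections round-trip through GMT", {
  coll <- generate_pathway_collection(sprintf("g%03d", 1:60), n_pathways = 12,
                                      size_range = c(3, 10),
                                      module_genes = sprintf("g%03d", 1:8),
                                      enriched_fraction = 0.25, rng_seed = 5)
  p <- tempfile(fileext = ".gmt")
  write_gmt(coll, p)
  back <- read_gmt(p)
  expect_equal(unclass(back)[names(coll)], unclass(coll)[names(coll)],
               ignore_attr = TRUE)
  expect_equal(attr(back, "descriptions"), attr(coll, "descriptions"))
})

test_that("pathway scores average with zero fill for unmapped genes", {
  x <- c(A = 0.4, B = 0.2)
  coll <- read_gmt(write_lines_tmp(
    c("both\td\tA\tB", "half\td\tA\tZ", "none\td\tY\tZ"), ".gmt"))
  tab <- score_pathways(x, coll)
  expect_equal(tab$mean_score[tab$pathway == "both"], 0.3)
  expect_equal(tab$mean_score[tab$pathway == "half"], 0.2)
  expect_equal(tab$mean_score[tab$pathway == "none"], 0)
  expect_equal(tab$n_mapped, c(2, 1, 0))
  # mapped-only denominator variant
  tabm <- score_pathways(x, coll, denominator = "mapped")
  expect_equal(tabm$mean_score[tabm$pathway == "half"], 0.4)
  # aggregate consistency: n_genes * mean recovers the zero-filled sums
  expect_equal(sum(tab$n_genes * tab$mean_score), 0.6 + 0.4 + 0)
})

test_that("top-fraction selection floors, ranks and breaks ties by name", {
  tab <- data.frame(pathway = sprintf("pw%02d", 1:20),
                    mean_score = c(20:2, 2) / 100)
  sel <- select_top_fraction(tab, 0.05)
  expect_equal(sel, "pw01")
  expect_error(select_top_fraction(tab, 0.01), "larger fraction")

  ties <- data.frame(pathway = c("b", "a", "c"), mean_score = rep(1, 3))
  expect_equal(select_top_fraction(ties, 1 / 3), "a")

  # idempotence: re-ranking the selected subset returns the same set
  tab2 <- data.frame(pathway = sprintf("p%03d", 1:40),
                     mean_score = rev(seq_len(40)) / 40)
  sel2 <- select_top_fraction(tab2, 0.25)
  again <- select_top_fraction(tab2[tab2$pathway %in% sel2, ], 0.999)
  expect_setequal(again, sel2[seq_along(again)])
})

test_that("overlap regions partition the union (brute-force oracle)", {
  A <- c(1, 2, 3); B <- c(2, 3, 4)
  ov <- overlap_counts(list(dis = A, drug = B))
  expect_equal(unname(ov$intersections[["AB"]]), 2)
  expect_equal(unname(ov$regions[c("A", "B", "AB")]), c(1, 1, 2),
               ignore_attr = TRUE)

  same <- overlap_counts(list(x = letters[1:5], y = letters[1:5]))
  expect_equal(unname(same$regions[["AB"]]), 5)
  expect_equal(sum(same$regions), same$union_size)

  # random 3- and 4-set instances vs element-by-element classification
  with_seed_sets <- function(k, seed) {
    set.seed(seed)
    stats::setNames(lapply(seq_len(k), function(i) sample(1:60, 25)),
                    paste0("s", seq_len(k)))
  }
  for (k in 3:4) {
    sets <- with_seed_sets(k, k + 10)
    ov <- overlap_counts(sets)
    expect_equal(sum(ov$regions), ov$union_size)
    aliases <- names(ov$sets)
    for (nm in names(ov$intersections)) {
      members <- strsplit(nm, "")[[1]]
      brute <- length(Reduce(intersect, sets[match(members, aliases)]))
      expect_equal(unname(ov$intersections[[nm]]), brute)
    }
    # exclusive regions by brute force too
    univ <- sort(unique(unlist(sets)))
    for (nm in names(ov$regions)) {
      members <- strsplit(nm, "")[[1]]
      inside <- Reduce(intersect, sets[match(members, aliases)])
      outside <- unlist(sets[match(setdiff(aliases, members), aliases)])
      brute <- length(setdiff(inside, outside))
      expect_equal(unname(ov$regions[[nm]]), brute)
    }
  }
  expect_error(overlap_counts(list(a = 1)), "2-4")
  expect_error(overlap_counts(list(a = 1, b = 2, c = 3, d = 4, e = 5)), "2-4")
})

test_that("percentages round half-up at the requested precision", {
  expect_equal(percent_shared(97, 236, 0), 41)
  expect_equal(percent_shared(81, 113, 1), 71.7)
  expect_equal(percent_shared(0, 50), 0)
  expect_equal(percent_shared(1, 8, 1), 12.5)
  expect_equal(percent_shared(1, 800, 1), 0.1)  # 0.125 rounds up, not to even
  expect_error(percent_shared(1, 0), "positive")
})
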