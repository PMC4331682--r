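mk_align <- function(...) alignment(list(...))
cl <- function(net, node) data.frame(network = net, node = node,
                                     stringsAsFactors = FALSE)

test_that("alignment accuracy counts induced pairs in the reference", {
  A <- mk_align(cl(c("A", "B"), c("u1", "v1")), cl(c("A", "B"), c("u2", "v2")))
  expect_equal(alignment_accuracy(A, A), 1)
  B <- mk_align(cl(c("A", "B"), c("u1", "v2")), cl(c("A", "B"), c("u2", "v1")))
  expect_equal(alignment_accuracy(A, B), 0)
  # A induces 4 cross pairs, 2 of them in the truth
  A2 <- mk_align(cl(c("A", "B", "A", "B"), c("u1", "v1", "u2", "v2")))
  T2 <- mk_align(cl(c("A", "B"), c("u1", "v1")), cl(c("A", "B"), c("u2", "v2")))
  expect_equal(alignment_accuracy(A2, T2), 0.5)
  empty <- alignment(list())
  expect_equal(alignment_accuracy(empty, T2), 0)
})

test_that("expected accuracy averages correspondence scores over pairs", {
  t1 <- toy1()
  res <- pair_correspondence(t1$A, t1$B, t1$sim)
  cs <- correspondence_set(network_set(t1$A, t1$B), list(res))
  one <- mk_align(cl(c("A", "B"), c("u2", "v2")))
  expect_equal(expected_accuracy(one, cs), 0.5, tolerance = 1e-9)
  # adding a zero-score pair strictly lowers the mean
  two <- mk_align(cl(c("A", "B", "B"), c("u2", "v2", "v1")))
  expect_lt(expected_accuracy(two, cs), expected_accuracy(one, cs))
  expect_error(expected_accuracy(alignment(list()), cs), "no cross-network")
})

test_that("filtering drops unannotated nodes and degenerate classes", {
  ann <- annotation_map(c("A", "A", "B"), c("u1", "u2", "v1"),
                        c("F1", "F1", "F1"))
  single_net <- mk_align(cl(c("A", "A"), c("u1", "u2")))
  expect_equal(n_classes(filter_classes(single_net, ann)), 0L)

  shrink <- mk_align(cl(c("A", "B"), c("u1", "v9")))  # v9 unannotated
  expect_equal(n_classes(filter_classes(shrink, ann)), 0L)

  keep <- mk_align(cl(c("A", "B"), c("u1", "v1")))
  f1 <- filter_classes(keep, ann)
  expect_equal(n_classes(f1), 1L)
  expect_equal(alignment_signature(filter_classes(f1, ann)),
               alignment_signature(f1))  # idempotent
})

test_that("CN and SPE follow the correct-class definition", {
  ann <- annotation_map(rep(c("A", "B"), each = 4),
                        c(paste0("u", 1:4), paste0("v", 1:4)),
                        c("F1", "F1", "F1", "F2", "F1", "F1", "F2", "F2"))
  both_ok <- mk_align(cl(c("A", "B"), c("u1", "v1")),
                      cl(c("A", "B", "A"), c("u2", "v2", "u3")))
  m <- class_metrics(both_ok, ann)
  expect_equal(m$CN, 5L); expect_equal(m$SPE, 1)

  # one correct class, one mixed (u4 is F2, v2 is F1)
  mixed <- mk_align(cl(c("A", "B"), c("u1", "v1")),
                    cl(c("A", "B"), c("u4", "v2")))
  m2 <- class_metrics(mixed, ann)
  expect_equal(m2$CN, 2L); expect_equal(m2$SPE, 0.5)

  all_mixed <- mk_align(cl(c("A", "B"), c("u4", "v1")))
  m3 <- class_metrics(all_mixed, ann)
  expect_equal(m3$CN, 0L); expect_equal(m3$SPE, 0)
  expect_error(class_metrics(alignment(list()), ann), "nothing to evaluate")
})

test_that("mean normalized entropy matches the closed formula", {
  ann <- annotation_map(rep("A", 4), paste0("u", 1:4),
                        c("F1", "F1", "F2", "F2"))
  half <- mk_align(cl(rep("A", 4), paste0("u", 1:4)))
  expect_equal(mean_normalized_entropy(half, ann), 1)

  pure <- annotation_map(rep("A", 3), paste0("u", 1:3), rep("F1", 3))
  expect_equal(mean_normalized_entropy(mk_align(cl(rep("A", 3), paste0("u", 1:3))),
                                       pure), 0)

  skew <- annotation_map(rep("A", 4), paste0("u", 1:4),
                         c("F1", "F1", "F1", "F2"))
  H <- mean_normalized_entropy(mk_align(cl(rep("A", 4), paste0("u", 1:4))), skew)
  expect_equal(H, 0.8113, tolerance = 1e-4)
})

test_that("conserved interactions require support from two networks", {
  t1 <- toy1()
  nets <- network_set(t1$A, t1$B)
  ann <- annotation_map(c("A", "A", "A", "B", "B"),
                        c("u1", "u2", "u3", "v1", "v2"),
                        c("F1", "F2", "F1", "F1", "F2"))
  A <- mk_align(cl(c("A", "B"), c("u2", "v2")),
                cl(c("A", "B", "A"), c("u1", "v1", "u3")))
  ci <- conserved_interactions(A, nets, ann)
  # u1-u2, u2-u3 (net A) and v1-v2 (net B) all run between the classes
  expect_equal(ci$CI, 3L)
  expect_equal(ci$COI, 3L)  # both classes are functionally pure

  # single-network support is not conserved
  C <- csrw_network("C", rbind(c("w1", "w2")))
  D <- csrw_network("D", rbind(c("x1", "x2")))
  nets2 <- network_set(C, D)
  ann2 <- annotation_map(c("C", "C", "D", "D"), c("w1", "w2", "x1", "x2"),
                         c("F1", "F2", "F1", "F2"))
  A2 <- alignment(list(cl(c("C", "D"), c("w1", "x1")),
                       cl(c("C", "D"), c("w2", "x2"))))
  # classes linked by w1-w2 in C and x1-x2 in D -> conserved (2 networks)
  expect_equal(conserved_interactions(A2, nets2, ann2)$CI, 2L)
  # remove D's edge: only network C links the classes -> not conserved
  D0 <- csrw_network("D", nodes = c("x1", "x2"))
  expect_equal(conserved_interactions(A2, network_set(C, D0), ann2)$CI, 0L)
})

test_that("coverage profile partitions classes and nodes by span", {
  A <- mk_align(cl(c("A", "B"), c("u2", "v2")),
                cl(c("A", "B", "A"), c("u1", "v1", "u3")))
  cov <- coverage_profile(A)
  expect_equal(cov$class_coverage, c("2" = 2L))
  expect_equal(cov$node_coverage, c("2" = 5L))
  expect_equal(sum(cov$node_coverage),
               sum(vapply(A$classes, nrow, integer(1))))
})

test_that("metrics_report assembles the full evaluation", {
  t1 <- toy1()
  nets <- network_set(t1$A, t1$B)
  ann <- annotation_map(c("A", "A", "A", "B", "B"),
                        c("u1", "u2", "u3", "v1", "v2"),
                        c("F1", "F2", "F1", "F1", "F2"))
  A <- mk_align(cl(c("A", "B"), c("u2", "v2")),
                cl(c("A", "B", "A"), c("u1", "v1", "u3")))
  rep <- metrics_report(A, nets, ann, truth = A)
  expect_equal(rep$CN, 5L)
  expect_equal(rep$SPE, 1)
  expect_equal(rep$MNE, 0)
  expect_equal(rep$CI, 3L)
  expect_equal(rep$accuracy, 1)
  tsv <- format_metrics_report(rep, style = "tsv")
  expect_length(tsv, 2L)
  expect_match(tsv[2], "\t1\\.000000\t0\\.000000\t")
})
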