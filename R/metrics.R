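#' Accuracy of an alignment against a reference
#'
#' Expands both alignments' equivalence classes into their induced
#' cross-network node pairs and returns the fraction of the predicted
#' pairs that also occur in the reference (true) alignment. Returns 0
#' when the predicted alignment induces no pairs.
#'
#' @param A Predicted [alignment()].
#' @param Astar Reference (true) [alignment()].
#' @return Fraction in \[0, 1\].
#' @export
alignment_accuracy <- function(A, Astar) {
  pa <- induced_pair_keys(A)
  if (length(pa) == 0L) return(0)
  pt <- induced_pair_keys(Astar)
  sum(pa %in% pt) / length(pa)
}

#' Expected accuracy of an alignment under correspondence scores
#'
#' The mean correspondence score over the cross-network pairs induced by
#' the alignment's classes; pairs without a recorded score count as 0.
#' Under the model assumption that scores approximate posterior
#' alignment probabilities, this estimates the expected fraction of
#' correctly aligned pairs.
#'
#' @param A An [alignment()].
#' @param cs A `csrw_corr_set` providing the per-pair score matrices.
#' @return Mean score (numeric scalar); errors if `A` induces no pairs.
#' @export
expected_accuracy <- function(A, cs) {
  p <- induced_pairs(A)
  if (nrow(p) == 0L) stop("alignment induces no cross-network pairs")
  total <- 0
  for (r in seq_len(nrow(p))) {
    C <- corr_matrix(cs, p$net1[r], p$net2[r])
    i <- match(p$node1[r], rownames(C))
    j <- match(p$node2[r], colnames(C))
    if (!is.na(i) && !is.na(j)) total <- total + C[i, j]
  }
  total / nrow(p)
}

#' Filter an alignment for functional evaluation
#'
#' Removes unannotated nodes from every class, then drops classes left
#' with fewer than two nodes or with all nodes from a single network.
#' Idempotent.
#'
#' @param A An [alignment()].
#' @param ann A `csrw_annmap`.
#' @return The filtered [alignment()].
#' @export
filter_classes <- function(A, ann) {
  kept <- list()
  for (cl in A$classes) {
    lab <- ann_lookup(ann, cl$network, cl$node)
    cl <- cl[!is.na(lab), , drop = FALSE]
    if (nrow(cl) < 2L) next
    if (length(unique(cl$network)) < 2L) next
    kept[[length(kept) + 1L]] <- cl
  }
  alignment(kept)
}

# Internal: logical vector, one per class: all members share one label.
class_correct <- function(A, ann) {
  vapply(A$classes, function(cl) {
    lab <- ann_lookup(ann, cl$network, cl$node)
    length(unique(lab)) == 1L && !anyNA(lab)
  }, logical(1))
}

#' Correct nodes and specificity of a filtered alignment
#'
#' A class is correct when all its nodes share one functional label.
#' CN is the total number of nodes in correct classes; SPE is the
#' fraction of classes that are correct.
#'
#' @param A A filtered [alignment()] (see [filter_classes()]).
#' @param ann A `csrw_annmap`.
#' @return List with elements `CN` (count) and `SPE` (fraction).
#' @export
class_metrics <- function(A, ann) {
  if (n_classes(A) == 0L) stop("nothing to evaluate: alignment has no classes")
  ok <- class_correct(A, ann)
  sizes <- vapply(A$classes, nrow, integer(1))
  list(CN = sum(sizes[ok]), SPE = mean(ok))
}

#' Mean normalized entropy of a filtered alignment
#'
#' Per class, with d distinct functional labels and label proportions
#' p_i, the normalized entropy is `H = -(1/log d) * sum p_i log p_i`
#' (base-independent); a pure class (d = 1) has H = 0. Returns the mean
#' over classes: 0 for a perfectly consistent alignment, up to 1 for
#' maximally mixed classes.
#'
#' @param A A filtered [alignment()].
#' @param ann A `csrw_annmap`.
#' @return Mean normalized entropy in \[0, 1\].
#' @export
mean_normalized_entropy <- function(A, ann) {
  if (n_classes(A) == 0L) stop("nothing to evaluate: alignment has no classes")
  H <- vapply(A$classes, function(cl) {
    lab <- ann_lookup(ann, cl$network, cl$node)
    lab <- lab[!is.na(lab)]
    p <- table(lab) / length(lab)
    d <- length(p)
    if (d <= 1L) return(0)
    -sum(p * log(p)) / log(d)
  }, numeric(1))
  mean(H)
}

#' Conserved interactions between equivalence classes
#'
#' Counts network edges running between two distinct equivalence
#' classes. An edge pattern between a class pair counts as conserved
#' only when at least two distinct networks contribute at least one such
#' edge; every contributing edge then counts toward CI. COI restricts
#' the count to class pairs in which both classes are correct (all
#' members share a label).
#'
#' @param A A filtered [alignment()].
#' @param networks A `csrw_network_set`.
#' @param ann A `csrw_annmap` (for class correctness).
#' @return List with elements `CI` and `COI` (counts, COI <= CI).
#' @export
conserved_interactions <- function(A, networks, ann) {
  if (n_classes(A) == 0L) return(list(CI = 0L, COI = 0L))
  cls_of <- new.env(parent = emptyenv(), hash = TRUE)
  for (k in seq_along(A$classes)) {
    cl <- A$classes[[k]]
    for (r in seq_len(nrow(cl))) {
      cls_of[[paste(cl$network[r], cl$node[r], sep = "\x1f")]] <- k
    }
  }
  # per (class pair, network): edge counts
  edge_net <- character(0); edge_pair <- character(0); edge_n <- integer(0)
  acc <- new.env(parent = emptyenv(), hash = TRUE)
  for (lab in names(networks)) {
    el <- network_edges(networks[[lab]])
    for (r in seq_len(nrow(el))) {
      cx <- cls_of[[paste(lab, el[r, 1], sep = "\x1f")]]
      cy <- cls_of[[paste(lab, el[r, 2], sep = "\x1f")]]
      if (is.null(cx) || is.null(cy) || cx == cy) next
      key <- paste(min(cx, cy), max(cx, cy), sep = ":")
      ent <- acc[[key]]
      if (is.null(ent)) ent <- list()
      ent[[lab]] <- (if (is.null(ent[[lab]])) 0L else ent[[lab]]) + 1L
      acc[[key]] <- ent
    }
  }
  ok <- class_correct(A, ann)
  CI <- 0L; COI <- 0L
  for (key in ls(acc)) {
    ent <- acc[[key]]
    if (length(ent) < 2L) next       # conservation needs >= 2 networks
    n_edges <- sum(unlist(ent))
    CI <- CI + n_edges
    kk <- as.integer(strsplit(key, ":", fixed = TRUE)[[1]])
    if (ok[kk[1]] && ok[kk[2]]) COI <- COI + n_edges
  }
  list(CI = CI, COI = COI)
}

#' Coverage profile of a filtered alignment
#'
#' @param A A filtered [alignment()].
#' @return List with `class_coverage` (named integer vector: k -> number
#'   of classes spanning exactly k networks) and `node_coverage` (k ->
#'   total members of those classes).
#' @export
coverage_profile <- function(A) {
  k <- vapply(A$classes, function(cl) length(unique(cl$network)), integer(1))
  sz <- vapply(A$classes, nrow, integer(1))
  ks <- sort(unique(k))
  list(
    class_coverage = stats::setNames(
      vapply(ks, function(x) sum(k == x), integer(1)), ks),
    node_coverage = stats::setNames(
      vapply(ks, function(x) sum(sz[k == x]), integer(1)), ks)
  )
}

#' Full evaluation report for an alignment
#'
#' Applies [filter_classes()] and assembles CN, SPE, MNE, CI, COI and
#' the coverage profile; when a reference alignment is supplied, the
#' pair-level accuracy is reported as well.
#'
#' @param A An [alignment()] (unfiltered).
#' @param networks A `csrw_network_set`.
#' @param ann A `csrw_annmap`.
#' @param truth Optional reference [alignment()].
#' @return A `csrw_metrics_report` list.
#' @export
metrics_report <- function(A, networks, ann, truth = NULL) {
  Af <- filter_classes(A, ann)
  if (n_classes(Af) == 0L) stop("no classes survive filtering")
  cm <- class_metrics(Af, ann)
  ci <- conserved_interactions(Af, networks, ann)
  cov <- coverage_profile(Af)
  rep <- list(
    n_classes = n_classes(A), n_classes_filtered = n_classes(Af),
    CN = cm$CN, SPE = cm$SPE,
    MNE = mean_normalized_entropy(Af, ann),
    CI = ci$CI, COI = ci$COI,
    class_coverage = cov$class_coverage,
    node_coverage = cov$node_coverage,
    accuracy = if (!is.null(truth)) alignment_accuracy(A, truth) else NA_real_
  )
  structure(rep, class = "csrw_metrics_report")
}

#' @export
print.csrw_metrics_report <- function(x, ...) {
  cat(format_metrics_report(x, style = "text"), sep = "\n")
  invisible(x)
}

#' Format a metrics report
#'
#' @param x A `csrw_metrics_report`.
#' @param style `"text"` for aligned key-value lines, `"tsv"` for one
#'   machine-readable tab-separated line (with header).
#' @return Character vector of output lines.
#' @export
format_metrics_report <- function(x, style = c("text", "tsv")) {
  style <- match.arg(style)
  covc <- paste(sprintf("%s:%d", names(x$class_coverage), x$class_coverage),
                collapse = ",")
  covn <- paste(sprintf("%s:%d", names(x$node_coverage), x$node_coverage),
                collapse = ",")
  if (style == "text") {
    out <- c(
      sprintf("classes          %d (evaluated %d after filtering)",
              x$n_classes, x$n_classes_filtered),
      sprintf("CN               %d", x$CN),
      sprintf("SPE              %.4f", x$SPE),
      sprintf("MNE              %.4f", x$MNE),
      sprintf("CI               %d", x$CI),
      sprintf("COI              %d", x$COI),
      sprintf("class_coverage   %s", covc),
      sprintf("node_coverage    %s", covn)
    )
    if (!is.na(x$accuracy)) {
      out <- c(out, sprintf("accuracy         %.4f", x$accuracy))
    }
    return(out)
  }
  header <- paste(c("classes", "classes_filtered", "CN", "SPE", "MNE",
                    "CI", "COI", "class_coverage", "node_coverage",
                    "accuracy"), collapse = "\t")
  vals <- paste(c(x$n_classes, x$n_classes_filtered, x$CN,
                  sprintf("%.6f", x$SPE), sprintf("%.6f", x$MNE),
                  x$CI, x$COI, covc, covn,
                  ifelse(is.na(x$accuracy), "NA", sprintf("%.6f", x$accuracy))),
                collapse = "\t")
  c(header, vals)
}
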