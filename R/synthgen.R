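#' Parameters of the duplication-based network growth models
#'
#' Three classic PPI network evolution models are supported:
#' DMC (duplication-mutation-complementation): a random node is
#' duplicated with all its edges; each inherited edge is then, with
#' probability `q_mod`, removed from either the parent or the copy
#' (equal odds), and a parent-copy edge is added with probability
#' `q_con`. DMR (duplication with random mutation): a random node is
#' duplicated, each inherited edge is kept with probability `1 - q_del`,
#' and on average `r_new` random edges are attached to the copy. CG
#' (crystal growth): a new node attaches to a random existing node and
#' to up to `m_att - 1` of its neighbours.
#'
#' The numeric defaults are this package's own realistic choices for
#' sparse PPI-like graphs (mean degree staying in the 2-6 range), not
#' values taken from any published benchmark.
#'
#' @param model One of `"DMC"`, `"DMR"`, `"CG"`.
#' @param seed_size Size of the initial ancestral seed graph.
#' @param q_mod DMC edge-modification probability.
#' @param q_con DMC parent-copy connection probability.
#' @param q_del DMR edge-deletion probability.
#' @param r_new DMR expected number of new random edges per duplication.
#' @param m_att CG attachment edges per new node.
#' @param rng_seed Integer seed; everything downstream is deterministic
#'   in it.
#' @return A `csrw_growth_params` list.
#' @export
growth_params <- function(model = c("DMC", "DMR", "CG"), seed_size = 50L,
                          q_mod = 0.4, q_con = 0.1, q_del = 0.4,
                          r_new = 1.0, m_att = 2L, rng_seed = 1L) {
  model <- match.arg(toupper(model[1]), c("DMC", "DMR", "CG"))
  stopifnot(seed_size >= 2, q_mod >= 0, q_mod <= 1, q_con >= 0, q_con <= 1,
            q_del >= 0, q_del <= 1, r_new >= 0, m_att >= 1)
  structure(list(model = model, seed_size = as.integer(seed_size),
                 q_mod = q_mod, q_con = q_con, q_del = q_del,
                 r_new = r_new, m_att = as.integer(m_att),
                 rng_seed = as.integer(rng_seed)),
            class = "csrw_growth_params")
}

# Internal: run fun() under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, fun) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fun()
}

# Internal: mutable adjacency helpers over an environment of character
# vectors (undirected, simple).
adj_add_edge <- function(env, a, b) {
  if (a == b || b %in% env[[a]]) return(invisible(FALSE))
  env[[a]] <- c(env[[a]], b)
  env[[b]] <- c(env[[b]], a)
  invisible(TRUE)
}
adj_del_edge <- function(env, a, b) {
  env[[a]] <- setdiff(env[[a]], b)
  env[[b]] <- setdiff(env[[b]], a)
  invisible(TRUE)
}

#' Grow a network under a duplication model
#'
#' Adds nodes one at a time until `target_size` is reached, following
#' the growth model in `params`. Nodes created by duplication (DMC, DMR)
#' inherit the parent's family id (paralogs); CG nodes found fresh
#' singleton families.
#'
#' @param base A [csrw_network()] to start from.
#' @param target_size Desired node count (>= size of `base`).
#' @param params A [growth_params()] (`rng_seed` drives all choices).
#' @param families Optional named character vector mapping every base
#'   node to a family id; defaults to one singleton family per node.
#' @param name_prefix Prefix for the names of newly created nodes.
#' @return List with `network` (the grown [csrw_network()]) and
#'   `families` (named character vector over all its nodes).
#' @export
grow_network <- function(base, target_size, params,
                         families = NULL, name_prefix = "g") {
  n0 <- n_nodes(base)
  if (target_size < n0) stop("target_size is smaller than the base network")
  if (is.null(families)) {
    families <- stats::setNames(paste0("fam_", base$nodes), base$nodes)
  }
  stopifnot(all(base$nodes %in% names(families)))
  if (target_size == n0) {
    return(list(network = base, families = families[base$nodes]))
  }
  env <- new.env(parent = emptyenv(), hash = TRUE)
  for (v in base$nodes) env[[v]] <- base$adj[[v]]
  nodes <- base$nodes
  fam <- as.list(families[base$nodes])

  res <- with_seed(params$rng_seed, function() {
    counter <- 0L
    while (length(nodes) < target_size) {
      counter <- counter + 1L
      child <- sprintf("%s%05d", name_prefix, counter)
      while (child %in% nodes) {
        counter <- counter + 1L
        child <- sprintf("%s%05d", name_prefix, counter)
      }
      if (params$model == "CG") {
        anchor <- sample(nodes, 1L)
        env[[child]] <- character(0)
        adj_add_edge(env, child, anchor)
        nb <- setdiff(env[[anchor]], child)
        k <- min(params$m_att - 1L, length(nb))
        if (k > 0L) {
          for (x in sample(nb, k)) adj_add_edge(env, child, x)
        }
        fam[[child]] <- paste0("fam_", child)
      } else {
        parent <- sample(nodes, 1L)
        inherited <- env[[parent]]
        env[[child]] <- character(0)
        if (params$model == "DMC") {
          for (x in inherited) adj_add_edge(env, child, x)
          for (x in inherited) {
            if (stats::runif(1) < params$q_mod) {
              if (stats::runif(1) < 0.5) adj_del_edge(env, parent, x)
              else adj_del_edge(env, child, x)
            }
          }
          if (stats::runif(1) < params$q_con) adj_add_edge(env, parent, child)
        } else {                        # DMR
          keep <- inherited[stats::runif(length(inherited)) >= params$q_del]
          for (x in keep) adj_add_edge(env, child, x)
          n_new <- stats::rpois(1, params$r_new)
          if (n_new > 0L) {
            cand <- setdiff(nodes, env[[child]])
            n_new <- min(n_new, length(cand))
            if (n_new > 0L) {
              for (x in sample(cand, n_new)) adj_add_edge(env, child, x)
            }
          }
        }
        fam[[child]] <- fam[[parent]]
      }
      nodes <- c(nodes, child)
    }
    list(nodes = nodes, fam = fam)
  })
  nodes <- res$nodes
  edges <- list()
  for (v in nodes) {
    nb <- env[[v]]
    nb <- nb[nb > v]
    if (length(nb) > 0L) edges[[v]] <- cbind(rep(v, length(nb)), nb)
  }
  em <- if (length(edges) > 0L) do.call(rbind, edges)
  else matrix(character(0), ncol = 2)
  net <- csrw_network(base$label, edges = em, nodes = nodes)
  list(network = net,
       families = stats::setNames(unlist(res$fam[net$nodes]), net$nodes))
}

# Internal: sparse connected seed graph (random recursive tree plus
# extra random edges), PPI-like mean degree around 4.
make_seed_graph <- function(label, size, seed) {
  with_seed(seed, function() {
    nodes <- sprintf("a%05d", seq_len(size))
    em <- NULL
    if (size > 1L) {
      to <- vapply(2:size, function(i) sample(i - 1L, 1L), integer(1))
      em <- cbind(nodes[2:size], nodes[to])
      n_extra <- size                    # roughly doubles the tree's edges
      e1 <- sample(size, n_extra, replace = TRUE)
      e2 <- sample(size, n_extra, replace = TRUE)
      ok <- e1 != e2
      em <- rbind(em, cbind(nodes[e1[ok]], nodes[e2[ok]]))
    }
    csrw_network(label, edges = em, nodes = nodes)
  })
}

#' Generate a benchmark family of related networks
#'
#' Emulates duplication-benchmark network families: a common ancestral
#' network is grown from a small seed to the smallest target size, then
#' copied once per network (speciation) and each copy grown
#' independently to its target size under the same model. The family id
#' of each ancestral node is shared by all its descendants across
#' networks, which defines the ground-truth equivalence classes.
#'
#' @param n_networks Number of networks (>= 2).
#' @param sizes Integer vector of target node counts, one per network.
#' @param params A [growth_params()].
#' @param labels Optional network labels; defaults to `A`, `B`, ...
#' @return List with `networks` (a `csrw_network_set`), `truth` (a
#'   `csrw_family_truth`: data frame `families` of (network, node,
#'   family), the true [alignment()] `alignment` over families spanning
#'   at least two networks, and the derived `annotations` map), and
#'   `ancestor` (the pre-speciation network).
#' @export
generate_family <- function(n_networks, sizes, params = growth_params(),
                            labels = NULL) {
  if (length(sizes) != n_networks) {
    stop("sizes must have one entry per network")
  }
  if (n_networks < 2L) stop("a family needs at least 2 networks")
  if (any(sizes < params$seed_size)) {
    stop("every target size must be at least seed_size")
  }
  if (is.null(labels)) {
    labels <- if (n_networks <= 26L) LETTERS[seq_len(n_networks)]
    else sprintf("N%02d", seq_len(n_networks))
  }
  stage_seeds <- with_seed(params$rng_seed, function()
    sample.int(.Machine$integer.max - 1L, n_networks + 2L))

  seed_net <- make_seed_graph("ancestor", params$seed_size, stage_seeds[1])
  anc_params <- params; anc_params$rng_seed <- stage_seeds[2]
  anc <- grow_network(seed_net, min(sizes), anc_params, name_prefix = "anc")

  nets <- vector("list", n_networks)
  fam_rows <- vector("list", n_networks)
  for (i in seq_len(n_networks)) {
    base_i <- anc$network
    base_i$label <- labels[i]
    p_i <- params; p_i$rng_seed <- stage_seeds[2 + i]
    g <- grow_network(base_i, sizes[i], p_i, families = anc$families,
                      name_prefix = paste0(tolower(labels[i]), "n"))
    nets[[i]] <- g$network
    fam_rows[[i]] <- data.frame(network = labels[i],
                                node = names(g$families),
                                family = unname(g$families),
                                stringsAsFactors = FALSE)
  }
  networks <- network_set(nets)
  families <- do.call(rbind, fam_rows)
  truth <- family_truth(families, networks)
  list(networks = networks, truth = truth, ancestor = anc$network)
}

#' Assemble ground-truth structures from a family table
#'
#' @param families Data frame with columns `network`, `node`, `family`.
#' @param networks Optional `csrw_network_set` for validation.
#' @return A `csrw_family_truth`: the `families` table, the true
#'   [alignment()] (one class per family with members in at least two
#'   networks) and the family-id `annotations` map.
#' @export
family_truth <- function(families, networks = NULL) {
  split_fam <- split(families, families$family)
  classes <- list()
  for (f in names(split_fam)) {
    cl <- split_fam[[f]]
    if (nrow(cl) < 2L || length(unique(cl$network)) < 2L) next
    classes[[length(classes) + 1L]] <-
      data.frame(network = cl$network, node = cl$node,
                 stringsAsFactors = FALSE)
  }
  structure(
    list(families = families,
         alignment = alignment(classes, networks = networks),
         annotations = annotation_map(families$network, families$node,
                                      families$family)),
    class = "csrw_family_truth"
  )
}

#' @export
print.csrw_family_truth <- function(x, ...) {
  cat(sprintf("<csrw_family_truth: %d nodes, %d families, %d true classes>\n",
              nrow(x$families), length(unique(x$families$family)),
              n_classes(x$alignment)))
  invisible(x)
}

#' Synthesize noisy similarity tables for a benchmark family
#'
#' Emulates BLAST-bit-score tables: every cross-network node pair in the
#' same family receives a score drawn from Gamma(shape 2, mean
#' `mu_true`); additionally each node gains, with probability `fpr`, one
#' spurious partner (uniform over the other network's nodes of a
#' different family) scored Gamma(shape 2, mean `mu_noise`).
#'
#' @param truth A `csrw_family_truth`.
#' @param mu_true Mean score of true (same-family) pairs; must exceed
#'   `mu_noise`. Default 100 (typical ortholog bit-score scale).
#' @param mu_noise Mean score of spurious pairs. Default 10.
#' @param fpr Per-node probability of a spurious partner in \[0, 1).
#'   Default 0.05.
#' @param rng_seed Integer seed.
#' @return Named list of [sim_table()]s, one per unordered network pair,
#'   keyed `"U-V"` in the family's network order.
#' @export
synth_similarity <- function(truth, mu_true = 100, mu_noise = 10,
                             fpr = 0.05, rng_seed = 1L) {
  stopifnot(mu_true > mu_noise, mu_noise > 0, fpr >= 0, fpr < 1)
  fam <- truth$families
  labels <- unique(fam$network)
  by_net <- split(fam, fam$network)
  with_seed(rng_seed, function() {
    out <- list()
    for (i in seq_len(length(labels) - 1L)) {
      for (j in (i + 1L):length(labels)) {
        fu <- by_net[[labels[i]]]; fv <- by_net[[labels[j]]]
        hit <- merge(fu[, c("node", "family")], fv[, c("node", "family")],
                     by = "family", suffixes = c(".u", ".v"))
        u <- hit$node.u; v <- hit$node.v
        sc <- stats::rgamma(length(u), shape = 2, rate = 2 / mu_true)
        if (fpr > 0) {
          spu <- fu[stats::runif(nrow(fu)) < fpr, , drop = FALSE]
          for (r in seq_len(nrow(spu))) {
            cand <- fv$node[fv$family != spu$family[r]]
            if (length(cand) == 0L) next
            u <- c(u, spu$node[r]); v <- c(v, sample(cand, 1L))
            sc <- c(sc, stats::rgamma(1, shape = 2, rate = 2 / mu_noise))
          }
          spv <- fv[stats::runif(nrow(fv)) < fpr, , drop = FALSE]
          for (r in seq_len(nrow(spv))) {
            cand <- fu$node[fu$family != spv$family[r]]
            if (length(cand) == 0L) next
            u <- c(u, sample(cand, 1L)); v <- c(v, spv$node[r])
            sc <- c(sc, stats::rgamma(1, shape = 2, rate = 2 / mu_noise))
          }
        }
        out[[paste(labels[i], labels[j], sep = "-")]] <-
          sim_table(labels[i], labels[j], u, v, pmax(sc, 1e-6))
      }
    }
    out
  })
}

#' Write a benchmark family to a directory
#'
#' Writes each network's edge list, every pairwise similarity table, the
#' family-id annotation table, the true alignment and a plain-text
#' `manifest.txt` of key=value parameter records.
#'
#' @param family Result of [generate_family()].
#' @param sims Result of [synth_similarity()].
#' @param dir Output directory (created if needed).
#' @param params The [growth_params()] used (recorded in the manifest).
#' @param extra Named character vector of extra manifest entries.
#' @return Invisibly, the directory.
#' @export
write_family <- function(family, sims, dir, params, extra = character(0)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (lab in names(family$networks)) {
    write_network(family$networks[[lab]],
                  file.path(dir, paste0("network_", lab, ".tsv")))
  }
  for (key in names(sims)) {
    write_similarity(sims[[key]],
                     file.path(dir, paste0("sim_", key, ".tsv")))
  }
  write_annotations(family$truth$annotations,
                    file.path(dir, "annotations.tsv"))
  write_alignment(family$truth$alignment,
                  file.path(dir, "true_alignment.tsv"))
  kv <- c(model = params$model, seed_size = params$seed_size,
          q_mod = params$q_mod, q_con = params$q_con, q_del = params$q_del,
          r_new = params$r_new, m_att = params$m_att,
          rng_seed = params$rng_seed,
          networks = paste(names(family$networks), collapse = ","),
          sizes = paste(vapply(family$networks, n_nodes, integer(1)),
                        collapse = ","),
          extra)
  con <- file(file.path(dir, "manifest.txt"), open = "wb")
  writeLines(paste0(names(kv), "=", kv), con, sep = "\n", useBytes = TRUE)
  close(con)
  invisible(dir)
}
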