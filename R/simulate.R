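#' Simulate the full (unreduced) context-sensitive random walk
#'
#' Monte-Carlo oracle for the reduced-chain computation: simulates the
#' CSRW over the full product space U x V, including the non-similar
#' pairs (set I) that the reduced matrix removes. At each step the walker
#' makes a match move into a similar neighbouring pair when one exists;
#' otherwise it performs an individual walk on one network, chosen with
#' probability proportional to network size, moving uniformly over the
#' current node's neighbours (renormalized over the moves that exist). A
#' walker with no move at all restarts from the similarity-proportional
#' restart distribution.
#'
#' Intended for small instances only: the full product space is
#' materialized.
#'
#' @param netU,netV The two networks.
#' @param sim The [sim_table()] for the pair.
#' @param steps Number of simulated steps (>= 1).
#' @param seed Integer seed; same seed gives identical output.
#' @return Named numeric vector over the M-pairs (names `u|v`), the
#'   fraction of M-visits spent at each pair (sums to 1 when any M-state
#'   was visited).
#' @export
simulate_walk <- function(netU, netV, sim, steps, seed) {
  stopifnot(steps >= 1)
  nU <- n_nodes(netU); nV <- n_nodes(netV)
  if (nU * nV > 250000) stop("full-chain simulation is for small instances")
  wU <- nU / (nU + nV); wV <- nV / (nU + nV)
  uid <- stats::setNames(seq_len(nU), netU$nodes)
  vid <- stats::setNames(seq_len(nV), netV$nodes)
  fid <- function(ui, vi) (ui - 1L) * nV + vi
  slook <- sim_lookup(sim)
  m <- n_pairs(sim)
  m_full <- fid(uid[sim$u], vid[sim$v])

  nfull <- nU * nV
  tgts <- vector("list", nfull)
  brks <- vector("list", nfull)
  for (ui in seq_len(nU)) {
    uc <- netU$nodes[ui]
    nu <- netU$adj[[uc]]
    for (vi in seq_len(nV)) {
      vc <- netV$nodes[vi]
      nv <- netV$adj[[vc]]
      st <- fid(ui, vi)
      tg <- integer(0); w <- numeric(0)
      if (length(nu) > 0L && length(nv) > 0L) {
        cand_u <- rep(nu, times = length(nv))
        cand_v <- rep(nv, each = length(nu))
        sc <- slook[node_pair_key(cand_u, cand_v)]
        hit <- !is.na(sc)
        if (any(hit)) {
          tg <- fid(uid[cand_u[hit]], vid[cand_v[hit]])
          w <- as.numeric(sc[hit])
        }
      }
      if (length(tg) == 0L) {
        if (length(nu) > 0L) {
          tg <- c(tg, fid(uid[nu], rep(vi, length(nu))))
          w <- c(w, rep(wU / length(nu), length(nu)))
        }
        if (length(nv) > 0L) {
          tg <- c(tg, fid(rep(ui, length(nv)), vid[nv]))
          w <- c(w, rep(wV / length(nv), length(nv)))
        }
      }
      if (length(tg) > 0L) {
        cw <- cumsum(w / sum(w))
        tgts[[st]] <- unname(tg)
        brks[[st]] <- cw[-length(cw)]   # breakpoints; target = findInterval + 1
      }
    }
  }
  s <- sim$score / sum(sim$score)
  s_brks <- cumsum(s)[-m]
  if (m == 1L) s_brks <- numeric(0)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  visits <- integer(nfull)
  state <- m_full[findInterval(stats::runif(1), s_brks) + 1L]
  chunk <- 100000L
  done <- 0L
  while (done < steps) {
    n <- min(chunk, steps - done)
    r <- stats::runif(n)
    for (t in seq_len(n)) {
      tg <- tgts[[state]]
      state <- if (is.null(tg)) {
        m_full[findInterval(r[t], s_brks) + 1L]
      } else {
        tg[findInterval(r[t], brks[[state]]) + 1L]
      }
      visits[state] <- visits[state] + 1L
    }
    done <- done + n
  }
  mv <- visits[m_full]
  tot <- sum(mv)
  freq <- if (tot > 0L) mv / tot else rep(0, m)
  stats::setNames(freq, paste(sim$u, sim$v, sep = "|"))
}
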