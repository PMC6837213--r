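# Discrete character history on the tree: parsimony ancestral states with
# transition counts, retention index, equal-rates Mk fitting by pruning, and
# stochastic character mapping with node posterior probabilities.

check_states <- function(tree, states) {
  states <- setNames(as.character(states), names(states))
  if (is.null(names(states))) {
    if (length(states) != length(tree$tip.label)) stop("states length != tips")
    names(states) <- tree$tip.label
  }
  miss <- setdiff(tree$tip.label, names(states))
  if (length(miss)) stop("tip(s) missing a state: ", paste(miss, collapse = ", "))
  states[tree$tip.label]
}

#' Parsimony ancestral state reconstruction (unordered multistate)
#'
#' Uniform-cost Sankoff dynamic programming with an up-pass (exact
#' most-parsimonious-reconstruction state sets per node; equivalent to
#' two-pass Fitch for an unordered character).  Transitions are enumerated
#' on one deterministic MPR: ties resolve to the parent's state when it is
#' optimal, otherwise to the state of smallest lexicographic rank.
#'
#' @param tree rooted, binary `phylo` (polytomies are an error).
#' @param states named character vector of tip states.
#' @return Object of class `parsimony_reconstruction`: `steps`, `node_sets`
#'   (MPR state set per internal node), `node_states` (the deterministic
#'   MPR), `transitions` (per-branch table), `ambiguous` flag.
#' @export
fitch_parsimony <- function(tree, states) {
  if (!ape::is.binary(tree)) stop("tree must be binary-resolved (no polytomies)")
  states <- check_states(tree, states)
  lev <- sort(unique(states))
  k <- length(lev)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  N <- ntip + nnode
  root <- ntip + 1L
  tre <- ape::reorder.phylo(tree, "postorder")
  edge <- tre$edge

  INF <- 1e9
  down <- matrix(0, N, k)            # min steps in subtree given node state
  for (i in seq_len(ntip)) {
    down[i, ] <- INF
    down[i, match(states[tree$tip.label[i]], lev)] <- 0
  }
  children <- split(edge[, 2L], edge[, 1L])
  # postorder edges: each child's subtree is complete before its edge, so a
  # parent accumulates one message per child edge
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1L]; c_ <- edge[e, 2L]
    msg <- vapply(seq_len(k), function(s)
      min(down[c_, ] + (seq_len(k) != s)), numeric(1))
    down[p, ] <- down[p, ] + msg
  }
  steps <- min(down[root, ])

  # up-pass in order of increasing depth from the root
  up <- matrix(0, N, k)
  parent_of <- integer(N); parent_of[] <- NA_integer_
  parent_of[edge[, 2L]] <- edge[, 1L]
  depth <- integer(N); depth[root] <- 0L
  for (e in rev(seq_len(nrow(edge))))  # reverse postorder = preorder
    depth[edge[e, 2L]] <- depth[edge[e, 1L]] + 1L
  internals <- root:N
  preorder <- internals[order(depth[internals])]
  for (p in preorder) {
    ch <- children[[as.character(p)]]
    for (c_ in ch) {
      sibs <- setdiff(ch, c_)
      sib_cost <- rep(0, k)
      for (s_ in sibs)
        sib_cost <- sib_cost + vapply(seq_len(k), function(s)
          min(down[s_, ] + (seq_len(k) != s)), numeric(1))
      base <- up[p, ] + sib_cost      # cost given parent state
      up[c_, ] <- vapply(seq_len(k), function(s)
        min(base + (seq_len(k) != s)), numeric(1))
    }
  }
  total <- down + up
  node_sets <- lapply(root:N, function(v) lev[total[v, ] == min(total[v, ])])
  names(node_sets) <- as.character(root:N)
  ambiguous <- any(lengths(node_sets) > 1L)

  # deterministic MPR: root = lexicographically first optimal state; child =
  # parent state if optimal, else first optimal state
  assign_ <- character(N)
  assign_[seq_len(ntip)] <- states[tree$tip.label]
  assign_[root] <- lev[which(down[root, ] == steps)][1L]
  for (p in preorder) {
    for (c_ in children[[as.character(p)]]) {
      if (c_ <= ntip) next
      ps <- match(assign_[p], lev)
      cost_given <- down[c_, ] + (seq_len(k) != ps)
      opt <- which(cost_given == min(cost_given))
      assign_[c_] <- if (ps %in% opt) lev[ps] else lev[opt][1L]
    }
  }
  tr_rows <- list()
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1L]; c_ <- edge[e, 2L]
    if (assign_[p] != assign_[c_])
      tr_rows[[length(tr_rows) + 1L]] <-
        data.frame(parent = p, child = c_, from = assign_[p], to = assign_[c_],
                   child_label = if (c_ <= ntip) tree$tip.label[c_] else NA_character_,
                   stringsAsFactors = FALSE)
  }
  transitions <- if (length(tr_rows)) do.call(rbind, tr_rows) else
    data.frame(parent = integer(), child = integer(), from = character(),
               to = character(), child_label = character())
  structure(list(steps = steps, node_sets = node_sets,
                 node_states = setNames(assign_[root:N], as.character(root:N)),
                 transitions = transitions, ambiguous = ambiguous,
                 levels = lev),
            class = "parsimony_reconstruction")
}

#' @export
print.parsimony_reconstruction <- function(x, ...) {
  cat(sprintf("Parsimony reconstruction: %d step(s), %d transition branch(es)%s\n",
              x$steps, nrow(x$transitions),
              if (x$ambiguous) ", ambiguous MPR sets present" else ""))
  invisible(x)
}

#' Retention index of a discrete character on a tree
#'
#' `RI = (g - s) / (g - m)` with `s` the parsimony steps, `m` the minimum
#' conceivable steps (observed states - 1), and `g` the maximum
#' (tips - max state frequency).  Invariant characters have no defined RI.
#'
#' @param tree rooted binary `phylo`.
#' @param states named tip states.
#' @return RI in `[0, 1]`, or `NA` for an invariant character.
#' @export
retention_index <- function(tree, states) {
  states <- check_states(tree, states)
  tab <- table(states)
  if (length(tab) < 2L) return(NA_real_)
  s <- fitch_parsimony(tree, states)$steps
  m <- length(tab) - 1
  g <- length(states) - max(tab)
  (g - s) / (g - m)
}

# ER transition probability: P(t)_ii and _ij for a k-state equal-rates Mk
er_prob <- function(rate, t, k) {
  e <- exp(-k * rate * t)
  list(same = 1 / k + (k - 1) / k * e, diff = 1 / k - e / k)
}

mk_er_loglik <- function(tree, states_idx, k, rate) {
  ntip <- length(tree$tip.label)
  N <- ntip + tree$Nnode
  tre <- ape::reorder.phylo(tree, "postorder")
  edge <- tre$edge
  elen <- tre$edge.length
  L <- matrix(0, N, k)
  for (i in seq_len(ntip)) L[i, states_idx[i]] <- 1
  L[(ntip + 1L):N, ] <- 1
  done <- rep(FALSE, N); done[seq_len(ntip)] <- TRUE
  scale_log <- 0
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1L]; c_ <- edge[e, 2L]
    pr <- er_prob(rate, elen[e], k)
    tot <- sum(L[c_, ])
    msg <- pr$diff * tot + (pr$same - pr$diff) * L[c_, ]
    L[p, ] <- L[p, ] * msg
    m <- max(L[p, ])
    if (m > 0 && (m < 1e-100 || m > 1e100)) { L[p, ] <- L[p, ] / m; scale_log <- scale_log + log(m) }
  }
  root <- ntip + 1L
  ll <- log(sum(L[root, ] / k)) + scale_log
  list(ll = ll, L = L, scale_log = scale_log)
}

#' Maximum-likelihood rate of the equal-rates Mk model
#'
#' Felsenstein pruning likelihood with a uniform root prior; bounded 1-D
#' search over the rate (tolerance 1e-8).
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param states named tip states (>= 2 observed states).
#' @return List with `rate`, `logLik`, `k`, `levels`.
#' @export
fit_mk_er <- function(tree, states) {
  states <- check_states(tree, states)
  lev <- sort(unique(states))
  k <- length(lev)
  if (k < 2L) stop("need at least two observed states")
  if (sum(tree$edge.length) <= 0) stop("zero-length tree")
  idx <- match(states[tree$tip.label], lev)
  th <- sum(tree$edge.length)
  obj <- function(lr) -mk_er_loglik(tree, idx, k, exp(lr))$ll
  opt <- optimize(obj, c(log(1e-8), log(1000 / th * length(tree$tip.label))), tol = 1e-8)
  list(rate = exp(opt$minimum), logLik = -opt$objective, k = k, levels = lev)
}

# simulate an ER CTMC path of duration t from state s; returns final state
# and number of changes
sim_er_path <- function(s, t, rate, k) {
  changes <- 0L
  cur <- s
  leave <- rate * (k - 1)
  tt <- 0
  if (leave <= 0) return(list(state = cur, changes = 0L))
  repeat {
    tt <- tt + rexp(1L, leave)
    if (tt > t) break
    other <- which(seq_len(k) != cur)
    cur <- if (length(other) == 1L) other else other[sample.int(length(other), 1L)]
    changes <- changes + 1L
  }
  list(state = cur, changes = changes)
}

#' Stochastic character mapping under the equal-rates Mk model
#'
#' Node states are drawn root-down from their conditional (pruning)
#' distributions; branch histories are then simulated conditional on the
#' endpoint states by rejection sampling (bounded attempts; on failure the
#' node draw is resampled, with a message).  Node posterior probabilities
#' are the frequencies across maps.
#'
#' @param tree rooted binary `phylo`.
#' @param states named tip states.
#' @param rate ER rate (> 0), e.g. from [fit_mk_er()].
#' @param n_sim number of maps (default 1000).
#' @param seed integer seed.
#' @param max_attempts rejection-sampling bound per branch (default 200).
#' @return Object of class `stochastic_map_set`: `posteriors` (node x state,
#'   rows sum to 1), `change_counts` (per map), `rate`, `n_sim`, `seed`.
#' @export
stochastic_maps <- function(tree, states, rate, n_sim = 1000L, seed = 1L,
                            max_attempts = 200L) {
  if (rate <= 0) stop("rate must be positive")
  states <- check_states(tree, states)
  lev <- sort(unique(states))
  k <- length(lev)
  if (k == 1L) {
    ntip <- length(tree$tip.label)
    post <- matrix(1, tree$Nnode, 1L,
                   dimnames = list(as.character((ntip + 1L):(ntip + tree$Nnode)), lev))
    return(structure(list(posteriors = post, change_counts = integer(n_sim),
                          rate = rate, n_sim = n_sim, seed = seed, levels = lev),
                     class = "stochastic_map_set"))
  }
  idx <- match(states[tree$tip.label], lev)
  ntip <- length(tree$tip.label)
  N <- ntip + tree$Nnode
  root <- ntip + 1L
  tre <- ape::reorder.phylo(tree, "postorder")
  edge <- tre$edge
  elen <- tre$edge.length

  # per-node downward partial likelihoods (unscaled within each node)
  Ldown <- matrix(1, N, k)
  Ldown[seq_len(ntip), ] <- 0
  for (i in seq_len(ntip)) Ldown[i, idx[i]] <- 1
  msgs <- matrix(0, nrow(edge), k)   # message from child c to parent along e
  for (e in seq_len(nrow(edge))) {
    c_ <- edge[e, 2L]
    pr <- er_prob(rate, elen[e], k)
    tot <- sum(Ldown[c_, ])
    msgs[e, ] <- pr$diff * tot + (pr$same - pr$diff) * Ldown[c_, ]
    p <- edge[e, 1L]
    Ldown[p, ] <- Ldown[p, ] * (msgs[e, ] / max(msgs[e, ]))
  }

  set.seed(seed)
  post_count <- matrix(0, tree$Nnode, k,
                       dimnames = list(as.character(root:N), lev))
  change_counts <- integer(n_sim)
  edges_pre <- nrow(edge):1L           # preorder traversal of edges
  n_resample <- 0L

  for (sim in seq_len(n_sim)) {
    node_state <- integer(N)
    node_state[seq_len(ntip)] <- idx
    pr_root <- Ldown[root, ] / sum(Ldown[root, ])
    node_state[root] <- sample.int(k, 1L, prob = pr_root)
    changes <- 0L
    for (e in edges_pre) {
      p <- edge[e, 1L]; c_ <- edge[e, 2L]
      pr <- er_prob(rate, elen[e], k)
      ps <- node_state[p]
      trans <- rep(pr$diff, k); trans[ps] <- pr$same
      w <- trans * Ldown[c_, ]
      if (c_ <= ntip) {
        cs <- idx[c_]
      } else {
        cs <- sample.int(k, 1L, prob = w / sum(w))
      }
      node_state[c_] <- cs
      # conditional branch history by rejection
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        path <- sim_er_path(ps, elen[e], rate, k)
        if (path$state == cs) { ok <- TRUE; break }
      }
      if (!ok) {
        n_resample <- n_resample + 1L
        if (c_ > ntip) {
          # resample the node draw and accept an unconditional path endpoint
          path <- sim_er_path(ps, elen[e], rate, k)
          node_state[c_] <- path$state
        }
      }
      changes <- changes + path$changes
    }
    change_counts[sim] <- changes
    for (v in root:N)
      post_count[v - ntip, node_state[v]] <- post_count[v - ntip, node_state[v]] + 1
  }
  if (n_resample > 0L)
    message("rejection sampling exhausted on ", n_resample,
            " branch draw(s); node draws resampled")
  structure(list(posteriors = post_count / n_sim, change_counts = change_counts,
                 rate = rate, n_sim = n_sim, seed = seed, levels = lev),
            class = "stochastic_map_set")
}
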