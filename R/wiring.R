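#' NCP wiring configuration
#'
#' Configuration of the sparse four-layer neural-circuit-policy graph:
#' sensory -> inter -> command -> motor, plus recurrent command-to-command
#' connections. Three stochastic mechanisms insert synapses: (1) each source
#' neuron draws `fanout_per_source` distinct candidate targets in the next
#' layer and inserts each with Bernoulli probability `p2`; (2) every target
#' left without afferents receives a Binomial(`p3`)-sized set of synapses
#' from the previous layer (redrawn until at least one lands, so no
#' non-sensory neuron is orphaned); (3) `n_recurrent_draws` candidate
#' recurrent command-to-command connections are each inserted with
#' probability `p4`. Synapse polarity is sampled uniformly from {-1, +1} at
#' wiring time and frozen.
#'
#' The defaults mirror the published architecture: 75 sensory neurons, 14
#' inter+command neurons (split 6/8 here) and 6 motor neurons, one per
#' abnormality class. By default the command-to-motor pair is wired densely
#' (`motor_fanin = "full"`): the motor layer is the readout, and when it
#' samples only 2-3 of the command neurons, whether a class is learnable
#' depends on the wiring lottery — command-state probes can carry a class
#' perfectly while the class's motor neuron, wired elsewhere, stays flat.
#' The trunk (sensory through command) stays sparse. Set
#' `motor_fanin = "sparse"` to run the stochastic mechanisms on the motor
#' pair as well.
#'
#' @param n_sensory,n_inter,n_command,n_motor layer sizes.
#' @param fanout_per_source candidate targets drawn per source neuron.
#' @param p2,p3,p4 insertion probabilities of the three mechanisms.
#' @param n_recurrent_draws candidate recurrent command connections.
#' @param motor_fanin `"full"` (dense command-to-motor readout, default) or
#'   `"sparse"` (mechanisms 1-2 wire the motor pair too).
#' @export
wiring_config <- function(n_sensory = 75, n_inter = 6, n_command = 8, n_motor = 6,
                          fanout_per_source = 4, p2 = 0.5, p3 = 0.6, p4 = 0.3,
                          n_recurrent_draws = 4, motor_fanin = c("full", "sparse")) {
  motor_fanin <- match.arg(motor_fanin)
  for (n in c(n_sensory, n_inter, n_command, n_motor)) {
    if (!is_count(n)) stopf("all layer sizes must be positive integers")
  }
  for (p in c(p2, p3, p4)) {
    if (!is.numeric(p) || p < 0 || p > 1) stopf("p2, p3, p4 must lie in [0, 1]")
  }
  if (!is_count(fanout_per_source) || !is_count(n_recurrent_draws)) {
    stopf("fanout_per_source and n_recurrent_draws must be positive integers")
  }
  structure(list(n_sensory = as.integer(n_sensory), n_inter = as.integer(n_inter),
                 n_command = as.integer(n_command), n_motor = as.integer(n_motor),
                 fanout_per_source = as.integer(fanout_per_source),
                 p2 = p2, p3 = p3, p4 = p4,
                 n_recurrent_draws = as.integer(n_recurrent_draws),
                 motor_fanin = motor_fanin),
            class = "wiring_config")
}

# sample() that never falls into the 1:x scalar interpretation
sample_vec <- function(x, n) x[sample.int(length(x), n)]

# Neuron ids are global: sensory 1..Ns, inter Ns+1.., command .., motor ..
wiring_layers <- function(cfg) {
  ns <- cfg$n_sensory; ni <- cfg$n_inter; nc <- cfg$n_command; nm <- cfg$n_motor
  list(sensory = seq_len(ns),
       inter = ns + seq_len(ni),
       command = ns + ni + seq_len(nc),
       motor = ns + ni + nc + seq_len(nm))
}

#' Build the sparse NCP wiring graph
#'
#' @param cfg a [wiring_config()].
#' @param seed RNG seed; the graph is fully determined by `(cfg, seed)`.
#' @return A `wiring_graph`: `layers` (id partition), `edges` (data.frame
#'   with `src`, `tgt`, `polarity`, `mechanism`), and the config.
#' @export
build_wiring <- function(cfg = wiring_config(), seed = 1) {
  if (!inherits(cfg, "wiring_config")) stopf("`cfg` must be a wiring_config")
  layers <- wiring_layers(cfg)
  with_seed(seed, {
    pairs <- list(c("sensory", "inter"), c("inter", "command"), c("command", "motor"))
    src <- integer(0); tgt <- integer(0); mech <- integer(0)
    for (pr in pairs) {
      if (pr[2] == "motor" && identical(cfg$motor_fanin, "full")) {
        # dense readout: every motor neuron reads every command neuron
        grid <- expand.grid(s = layers$command, t = layers$motor)
        src <- c(src, grid$s); tgt <- c(tgt, grid$t)
        mech <- c(mech, rep.int(4L, nrow(grid)))
        next
      }
      sources <- layers[[pr[1]]]; targets <- layers[[pr[2]]]
      if (length(sources) == 0) stopf("layer '%s' has no eligible sources", pr[1])
      # mechanism 1: per-source Bernoulli(p2) insertion over distinct candidates
      fo <- min(cfg$fanout_per_source, length(targets))
      for (s in sources) {
        cand <- if (fo == length(targets)) targets else sample_vec(targets, fo)
        ins <- cand[stats::runif(fo) < cfg$p2]
        src <- c(src, rep.int(s, length(ins))); tgt <- c(tgt, ins)
        mech <- c(mech, rep.int(1L, length(ins)))
      }
      # mechanism 2: top-up for orphan targets, >= 1 afferent guaranteed
      for (t in setdiff(targets, unique(tgt[tgt %in% targets]))) {
        m <- 0L
        while (m < 1L) m <- stats::rbinom(1, length(sources), cfg$p3)
        m <- min(m, length(sources))
        picks <- if (m == length(sources)) sources else sample_vec(sources, m)
        src <- c(src, picks); tgt <- c(tgt, rep.int(t, m))
        mech <- c(mech, rep.int(2L, m))
      }
    }
    # mechanism 3: recurrent command -> command
    cmd <- layers$command
    for (k in seq_len(cfg$n_recurrent_draws)) {
      if (stats::runif(1) < cfg$p4) {
        src <- c(src, sample_vec(cmd, 1)); tgt <- c(tgt, sample_vec(cmd, 1))
        mech <- c(mech, 3L)
      }
    }
    edges <- data.frame(src = src, tgt = tgt, mechanism = mech)
    # collapse duplicates (keep the first occurrence)
    edges <- edges[!duplicated(edges[c("src", "tgt")]), , drop = FALSE]
    edges$polarity <- sample(c(-1, 1), nrow(edges), replace = TRUE)
    # polarity balance: a neuron whose afferents all share one sign can only
    # be driven one way by its inputs, which freezes its response; when a
    # target has >= 2 afferents, flip a random one so both signs occur
    for (tt in unique(edges$tgt)) {
      aff <- which(edges$tgt == tt)
      if (length(aff) >= 2 && length(unique(edges$polarity[aff])) == 1) {
        flip <- sample_vec(aff, 1)
        edges$polarity[flip] <- -edges$polarity[flip]
      }
    }
    rownames(edges) <- NULL
    structure(list(layers = layers, edges = edges, config = cfg, seed = seed),
              class = "wiring_graph")
  })
}

#' @export
print.wiring_graph <- function(x, ...) {
  l <- x$layers
  cat(sprintf("<wiring_graph> %d sensory / %d inter / %d command / %d motor, %d synapses (sparsity %.3f)\n",
              length(l$sensory), length(l$inter), length(l$command), length(l$motor),
              nrow(x$edges), sparsity(x)))
  invisible(x)
}

# Feasible slot count: consecutive layer pairs plus command recurrence.
feasible_slots <- function(g) {
  l <- g$layers
  length(l$sensory) * length(l$inter) + length(l$inter) * length(l$command) +
    length(l$command) * length(l$motor) + length(l$command)^2
}

#' Wiring sparsity
#'
#' Fraction of feasible synapse slots (consecutive layer pairs plus
#' command-to-command recurrence) actually occupied.
#' @param g a `wiring_graph`.
#' @export
sparsity <- function(g) {
  if (!inherits(g, "wiring_graph")) stopf("`g` must be a wiring_graph")
  nrow(g$edges) / feasible_slots(g)
}

layer_of <- function(g, ids) {
  l <- g$layers
  out <- character(length(ids))
  for (nm in names(l)) out[ids %in% l[[nm]]] <- nm
  out
}

#' Validate wiring-graph invariants
#'
#' Checks layer discipline (edges only between consecutive layers or
#' command recurrence), the no-orphan guarantee (every non-sensory neuron
#' has at least one afferent), and polarity values.
#'
#' @param g a `wiring_graph`.
#' @return character vector of human-readable violations; empty if valid.
#' @export
validate_wiring <- function(g) {
  v <- character(0)
  e <- g$edges
  sl <- layer_of(g, e$src); tl <- layer_of(g, e$tgt)
  ok <- (sl == "sensory" & tl == "inter") | (sl == "inter" & tl == "command") |
    (sl == "command" & tl == "motor") | (sl == "command" & tl == "command")
  if (any(!ok)) {
    v <- c(v, sprintf("edge %d->%d violates layer discipline (%s->%s)",
                      e$src[!ok], e$tgt[!ok], sl[!ok], tl[!ok]))
  }
  if (!all(e$polarity %in% c(-1, 1))) {
    bad <- which(!(e$polarity %in% c(-1, 1)))
    v <- c(v, sprintf("edge %d->%d has invalid polarity %g",
                      e$src[bad], e$tgt[bad], e$polarity[bad]))
  }
  non_sensory <- unlist(g$layers[c("inter", "command", "motor")], use.names = FALSE)
  orphan <- setdiff(non_sensory, unique(e$tgt))
  if (length(orphan)) {
    v <- c(v, sprintf("neuron %d (%s) has no incoming synapse",
                      orphan, layer_of(g, orphan)))
  }
  v
}

# Internal edge layout used by the cells: presynaptic values are indexed in
# a stacked vector V = [state neurons (inter, command, motor); sensory
# inputs]. Returns integer indices and per-edge polarity, split into
# input-sourced and state-sourced groups for efficiency.
wiring_edge_layout <- function(g) {
  l <- g$layers
  ns <- length(l$sensory)
  n_state <- length(l$inter) + length(l$command) + length(l$motor)
  # map global id -> state index (1..n_state) or V index
  state_ids <- c(l$inter, l$command, l$motor)
  v_index <- integer(max(unlist(l)))
  v_index[state_ids] <- seq_len(n_state)
  v_index[l$sensory] <- n_state + seq_len(ns)
  e <- g$edges
  list(
    n_state = n_state, n_input = ns,
    src = v_index[e$src], tgt = v_index[e$tgt],
    polarity = e$polarity,
    from_input = v_index[e$src] > n_state,
    motor_idx = seq.int(n_state - length(l$motor) + 1L, n_state)
  )
}
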