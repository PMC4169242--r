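#' Construct a synchronous Boolean network
#'
#' Nodes take values in \{0,1\}. Each node either has an update rule — an
#' expression over node names using the operators `AND`, `OR`, `NOT` and
#' `NAND` (e.g. `"NAND(dFOXO, PNT)"`, `"NOT AOP"`) — or is *free*: a free
#' node holds whatever value it was initialised with, modelling an input
#' whose own regulation is outside the network. Clamped nodes are fixed at a
#' constant regardless of any rule, modelling constitutive activation or
#' inactivation.
#'
#' @param rules Named list/character vector mapping node names to rule
#'   expressions; nodes mentioned in rules but absent from `names(rules)` are
#'   free.
#' @param clamps Named numeric/logical vector of nodes fixed at 0 or 1.
#' @param target Name of the readout node; default `"lifespan"`.
#' @return An object of class `boolean_network`.
#' @export
boolean_network <- function(rules, clamps = c(), target = "lifespan") {
  rules <- as.list(rules)
  parsed <- lapply(rules, .parse_rule)
  rule_inputs <- unique(unlist(lapply(parsed, function(p) p$inputs)))
  nodes <- unique(c(names(rules), rule_inputs, target, names(clamps)))
  unknown <- setdiff(rule_inputs, nodes)
  if (length(unknown)) stop("rule inputs refer to unknown nodes: ",
                            paste(unknown, collapse = ", "))
  if (!target %in% nodes) stop("target must be a node")
  clamps <- .check_clamps(clamps, nodes)
  structure(list(nodes = nodes, rules = parsed, clamps = clamps,
                 target = target),
            class = "boolean_network")
}

.check_clamps <- function(clamps, nodes) {
  if (length(clamps) == 0) return(stats::setNames(numeric(0), character(0)))
  if (is.null(names(clamps)) || any(names(clamps) == "")) {
    stop("clamps must be a named vector")
  }
  if (!all(names(clamps) %in% nodes)) {
    stop("clamped nodes must exist in the network: ",
         paste(setdiff(names(clamps), nodes), collapse = ", "))
  }
  v <- as.numeric(clamps)
  if (!all(v %in% c(0, 1))) stop("clamp values must be 0 or 1")
  stats::setNames(v, names(clamps))
}

# translate AND/OR/NOT word operators to R logical operators; NAND stays a
# function call supplied in the evaluation environment
.parse_rule <- function(text) {
  txt <- as.character(text)
  r <- gsub("\\bAND\\b", "&", txt)
  r <- gsub("\\bOR\\b", "|", r)
  r <- gsub("\\bNOT\\b", "!", r)
  expr <- tryCatch(str2lang(r),
                   error = function(e) stop("cannot parse rule '", txt, "'"))
  vars <- setdiff(all.vars(expr), "NAND")
  list(expr = expr, inputs = vars, text = txt)
}

.rule_env <- function(state) {
  env <- list2env(as.list(state == 1), parent = baseenv())
  env$NAND <- function(...) !all(...)
  env
}

#' Parse a Boolean network from its text definition
#'
#' One rule per line in the form `node <- EXPR` (blank lines and `#` comments
#' ignored), with the operator vocabulary of [boolean_network()].
#'
#' @param lines Character vector of definition lines, or a file path.
#' @param clamps,target Passed to [boolean_network()].
#' @return A `boolean_network`.
#' @export
parse_network <- function(lines, clamps = c(), target = "lifespan") {
  if (length(lines) == 1 && file.exists(lines)) lines <- readLines(lines)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  m <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*<-\\s*(.+)$",
                                 lines))
  bad <- vapply(m, length, integer(1)) != 3
  if (any(bad)) stop("malformed rule line: ", lines[bad][1])
  rules <- stats::setNames(lapply(m, `[`, 3), vapply(m, `[`, "", 2))
  boolean_network(rules, clamps = clamps, target = target)
}

#' The feed-forward dFOXO/AOP/PNT/lifespan model
#'
#' dFOXO activates AOP, AOP represses PNT, and lifespan is governed by a NAND
#' of dFOXO and PNT: only the *combined* activity of the two transcription
#' factors is detrimental. dFOXO itself is a free input node.
#'
#' @return A `boolean_network`.
#' @export
build_feedforward_model <- function() {
  boolean_network(list(
    AOP = "dFOXO",
    PNT = "NOT AOP",
    lifespan = "NAND(dFOXO, PNT)"
  ))
}

#' The linear dFOXO/AOP/PNT/lifespan model
#'
#' A simple cascade: dFOXO activates AOP, AOP represses PNT, PNT represses
#' lifespan; no direct dFOXO-lifespan edge. dFOXO is free.
#'
#' @return A `boolean_network`.
#' @export
build_linear_model <- function() {
  boolean_network(list(
    AOP = "dFOXO",
    PNT = "NOT AOP",
    lifespan = "NOT PNT"
  ))
}

#' One synchronous update of a Boolean network
#'
#' All ruled, unclamped nodes update simultaneously from the previous state;
#' clamped nodes keep their clamp value; free unclamped nodes keep their
#' previous value.
#'
#' @param net A `boolean_network`.
#' @param state Named numeric vector assigning 0/1 to every node.
#' @param clamps Clamp set; defaults to the network's own.
#' @return The next state (named 0/1 vector).
#' @export
synchronous_step <- function(net, state, clamps = net$clamps) {
  if (!all(net$nodes %in% names(state)) ||
      !all(state[net$nodes] %in% c(0, 1))) {
    stop("`state` must assign 0 or 1 to every node")
  }
  env <- .rule_env(state)
  nxt <- state
  for (node in names(net$rules)) {
    nxt[node] <- as.numeric(eval(net$rules[[node]]$expr, env))
  }
  if (length(clamps)) nxt[names(clamps)] <- clamps
  nxt
}

# run the deterministic dynamics from one initial state and return the target
# value at step n_transitions, short-circuiting once the trajectory revisits
# a state (period-P cycle => state at n is state at entry + (n - entry) mod P)
.target_at <- function(net, state, clamps, target, n_transitions) {
  if (length(clamps)) state[names(clamps)] <- clamps
  seen <- new.env(parent = emptyenv())
  trace <- list()
  cur <- state
  for (t in 0:n_transitions) {
    key <- paste(cur[net$nodes], collapse = "")
    prev <- seen[[key]]
    if (!is.null(prev)) {
      period <- t - prev
      idx <- prev + (n_transitions - prev) %% period
      return(trace[[idx + 1]][[target]])
    }
    seen[[key]] <- t
    trace[[t + 1]] <- cur
    if (t == n_transitions) return(cur[[target]])
    cur <- synchronous_step(net, cur, clamps)
  }
  cur[[target]]
}

#' Probability that a node is active after many state transitions
#'
#' Initial states are uniform over \{0,1\} for every unclamped node (clamped
#' nodes start at their clamp value). In `exact` mode every initial state is
#' enumerated and the target's value at step `n_transitions` is averaged; in
#' `monte_carlo` mode `n_runs` initial states are sampled with a seeded RNG.
#' For deterministic networks the trajectory enters a cycle within at most
#' `2^n` steps, so the value at step 1000 is computed by cycle detection
#' rather than literal iteration.
#'
#' @param net A `boolean_network`.
#' @param target Readout node; defaults to the network's target.
#' @param clamps Named 0/1 vector of clamped nodes (overrides the network's
#'   clamp set for this run).
#' @param n_transitions Number of synchronous updates; default 1000.
#' @param mode `"exact"` (default) or `"monte_carlo"`.
#' @param n_runs Monte-Carlo sample size; default 10000.
#' @param seed Seed for Monte-Carlo initial-state sampling.
#' @return A list of class `simulation_result`: `probability_target_active`,
#'   `mode`, `n_transitions`, and for Monte-Carlo runs `n_runs` and `seed`.
#' @export
simulate_probability <- function(net, target = net$target, clamps = c(),
                                 n_transitions = 1000,
                                 mode = c("exact", "monte_carlo"),
                                 n_runs = 10000, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(target %in% net$nodes)
  clamps <- .check_clamps(clamps, net$nodes)
  open <- setdiff(net$nodes, names(clamps))
  base <- stats::setNames(rep(0, length(net$nodes)), net$nodes)
  if (mode == "exact") {
    grid <- if (length(open)) {
      as.matrix(expand.grid(rep(list(c(0, 1)), length(open))))
    } else matrix(numeric(0), nrow = 1, ncol = 0)
    vals <- apply(grid, 1, function(row) {
      st <- base
      if (length(open)) st[open] <- row
      .target_at(net, st, clamps, target, n_transitions)
    })
    res <- list(probability_target_active = mean(vals), mode = "exact",
                n_transitions = n_transitions)
  } else {
    if (n_runs < 1) stop("`n_runs` must be >= 1")
    set.seed(seed)
    draws <- matrix(stats::rbinom(n_runs * length(open), 1, 0.5),
                    nrow = n_runs)
    vals <- apply(draws, 1, function(row) {
      st <- base
      if (length(open)) st[open] <- row
      .target_at(net, st, clamps, target, n_transitions)
    })
    res <- list(probability_target_active = mean(vals), mode = "monte_carlo",
                n_transitions = n_transitions, n_runs = n_runs, seed = seed)
  }
  class(res) <- "simulation_result"
  res
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("P(target = 1) = %.4f after %d transitions (%s%s)\n",
              x$probability_target_active, x$n_transitions, x$mode,
              if (x$mode == "monte_carlo")
                sprintf(", %d runs", x$n_runs) else ""))
  invisible(x)
}

#' Compare Boolean models across clamping scenarios
#'
#' Computes the exact probability that the target is active under each
#' clamping scenario for each model, and flags *synergy*: whether clamping
#' both factors gives a strictly lower probability than either factor alone —
#' the signature a feed-forward circuit can show and a linear cascade cannot.
#'
#' @param models Named list of `boolean_network`s; default the feed-forward
#'   and linear dFOXO/AOP/PNT models.
#' @param scenarios Named list of clamp vectors; default clamping dFOXO, PNT,
#'   or both, active.
#' @param n_transitions Transitions per simulation; default 1000.
#' @return A data.frame with one row per model: one probability column per
#'   scenario plus a logical `synergy` column.
#' @export
compare_models <- function(models = list(feedforward = build_feedforward_model(),
                                         linear = build_linear_model()),
                           scenarios = list(dFOXO = c(dFOXO = 1),
                                            PNT = c(PNT = 1),
                                            both = c(dFOXO = 1, PNT = 1)),
                           n_transitions = 1000) {
  probs <- t(vapply(models, function(m) {
    vapply(scenarios, function(cl) {
      simulate_probability(m, clamps = cl, n_transitions = n_transitions,
                           mode = "exact")$probability_target_active
    }, numeric(1))
  }, numeric(length(scenarios))))
  out <- data.frame(model = names(models), probs, row.names = NULL,
                    stringsAsFactors = FALSE)
  if (all(c("dFOXO", "PNT", "both") %in% names(scenarios))) {
    out$synergy <- out$both < pmin(out$dFOXO, out$PNT)
  }
  out
}
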