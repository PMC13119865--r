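# Short-run decision tree: three treatment rounds, hospital admission,
# recovery or death. Both arms share one topology; they differ only in the
# first-line antibiotic probability, the arm-specific improvement and
# hospitalisation probabilities, and the panel-test cost applied once at the
# intervention root.

.severity_classes <- c("mild", "moderate", "severe_full", "severe_partial", "dead")

# Probability references are strings resolved against the parameter set at
# rollback time: "intervention.improve_initial_ab" looks under
# probabilities$intervention, "tree.second_ab_share" under the tree block,
# and a leading "!" takes the complement. Numeric literals pass through.
resolve_prob <- function(ref, params) {
  if (is.numeric(ref)) return(ref)
  if (startsWith(ref, "!")) return(1 - resolve_prob(substring(ref, 2), params))
  keys <- strsplit(ref, ".", fixed = TRUE)[[1]]
  if (keys[1] == "tree") {
    v <- params$tree[[keys[2]]]
    if (is.null(v)) stop("unresolved probability reference: ", ref, call. = FALSE)
    return(v)
  }
  it <- params$probabilities[[keys[1]]][[keys[2]]]
  if (is.null(it)) stop("unresolved probability reference: ", ref, call. = FALSE)
  it$mean
}

chance_node <- function(label, branches, cost_items = NULL) {
  structure(list(kind = "chance", label = label, branches = branches,
                 cost_items = cost_items), class = "tree_node")
}

terminal_node <- function(label, class, cost_items = NULL) {
  stopifnot(class %in% .severity_classes)
  structure(list(kind = "terminal", label = label, class = class,
                 cost_items = cost_items), class = "tree_node")
}

branch <- function(p, node) list(p = p, node = node)

# Expand a configured cost bundle into a named quantity vector.
bundle_items <- function(params, name, extra = NULL) {
  b <- params$tree$bundles[[name]]
  if (is.null(b)) stop("unknown cost bundle: ", name, call. = FALSE)
  out <- unlist(b)
  if (!is.null(extra)) out <- c(out, extra)
  out
}

node_cost <- function(node, params) {
  if (is.null(node$cost_items)) return(0)
  sum(vapply(names(node$cost_items), function(item)
    node$cost_items[[item]] * params$costs[[item]]$mean, numeric(1)))
}

#' Build the short-run pathway tree for one arm
#'
#' Constructs the arm's decision tree from the configured bundles and
#' probability references. Both arms share the topology: a first-line split
#' between antibiotics alone and steroids plus antibiotics (driven by the
#' arm's antibiotic probability), improvement or deterioration after each of
#' up to three treatment rounds, then hospital admission ending in full
#' recovery, partial recovery or death. The panel-test cost is attached
#' exactly once, at the intervention-arm root; the control tree never
#' carries it.
#'
#' @param arm `"intervention"` or `"control"`.
#' @param params A `copd_params` object.
#' @return The root `tree_node`.
#' @export
build_arm_tree <- function(arm = c("intervention", "control"), params) {
  arm <- match.arg(arm)
  hosp_ab <- paste0("hospitalisation.", arm, "_ab")
  hosp_st_ab <- paste0("hospitalisation.", arm, "_st_ab")
  ref <- function(nm) paste0(arm, ".", nm)

  third <- function(p_hosp_ref) {
    survivors <- chance_node(
      "recovery after discharge",
      list(branch("tree.p_full_given_survival",
                  terminal_node("fully recovered after admission", "severe_full")),
           branch("!tree.p_full_given_survival",
                  terminal_node("partially recovered after admission", "severe_partial"))),
      cost_items = bundle_items(params, "post_discharge"))
    admitted <- chance_node(
      "hospital admission",
      list(branch("shared.mortality_after_admission",
                  terminal_node("died after admission", "dead")),
           branch("!shared.mortality_after_admission", survivors)),
      cost_items = bundle_items(params, "admission"))
    admission_stage <- chance_node(
      "admission decision",
      list(branch(p_hosp_ref, admitted),
           branch(paste0("!", p_hosp_ref),
                  terminal_node("managed in community, partial recovery",
                                "severe_partial",
                                cost_items = bundle_items(params, "community_care")))))
    chance_node(
      "third treatment",
      list(branch("shared.improve_third",
                  terminal_node("recovered after third treatment", "severe_full")),
           branch("!shared.improve_third", admission_stage)),
      cost_items = bundle_items(params, "third"))
  }

  second_ab <- chance_node(
    "second antibiotic course",
    list(branch(ref("improve_second_ab"),
                terminal_node("recovered after second antibiotics", "moderate")),
         branch(paste0("!", ref("improve_second_ab")), third(hosp_ab))),
    cost_items = bundle_items(params, "second_ab"))
  second_ab_ae <- chance_node(
    "second treatment with A&E attendance",
    list(branch(ref("improve_second_ab_ae"),
                terminal_node("recovered after antibiotics and A&E", "moderate")),
         branch(paste0("!", ref("improve_second_ab_ae")), third(hosp_ab))),
    cost_items = bundle_items(params, "second_ab_ae"))
  ab_branch <- chance_node(
    "first-line antibiotics",
    list(branch(ref("improve_initial_ab"),
                terminal_node("recovered after initial antibiotics", "mild")),
         branch(paste0("!", ref("improve_initial_ab")),
                chance_node("second-line routing after antibiotics",
                            list(branch("tree.second_ab_share", second_ab),
                                 branch("!tree.second_ab_share", second_ab_ae))))),
    cost_items = bundle_items(params, "first_ab"))

  st_ab_extra <- NULL
  if (arm == "control" && isTRUE(params$tree$viral_alt_antibiotics))
    st_ab_extra <- c(alternative_antibiotics = 1)
  second_st_ab <- chance_node(
    "second steroid and antibiotic course",
    list(branch(ref("improve_second_st_ab"),
                terminal_node("recovered after second steroids+antibiotics", "moderate")),
         branch(paste0("!", ref("improve_second_st_ab")), third(hosp_st_ab))),
    cost_items = bundle_items(params, "second_st_ab"))
  st_ab_branch <- chance_node(
    "first-line steroids and antibiotics",
    list(branch(ref("improve_initial_st_ab"),
                terminal_node("recovered after initial steroids+antibiotics", "mild")),
         branch(paste0("!", ref("improve_initial_st_ab")), second_st_ab)),
    cost_items = bundle_items(params, "first_st_ab", extra = st_ab_extra))

  root_costs <- if (arm == "intervention") c(rp21_test = 1) else NULL
  chance_node(
    paste0(arm, " arm"),
    list(branch(ref("antibiotics_initial"), ab_branch),
         branch(paste0("!", ref("antibiotics_initial")), st_ab_branch)),
    cost_items = root_costs)
}

terminal_payoff <- function(class, params) {
  switch(class,
         dead = params$utilities$recovery$dead$mean,
         severe_partial = params$utilities$recovery$partially_recovered$mean,
         params$utilities$recovery$fully_recovered$mean)
}

#' Roll back a pathway tree to its expected outcomes
#'
#' Computes the probability-weighted expected cost, expected utility payoff
#' and the distribution over short-run severity classes (mild, moderate,
#' severe with full or partial recovery, dead) by recursive expectation over
#' the tree. Branch probabilities at each chance node must resolve to a unit
#' sum (tolerance 1e-12); zero-probability branches are pruned.
#'
#' @param tree Root `tree_node` from [build_arm_tree()].
#' @param params A `copd_params` object.
#' @return An object of class `arm_expectation`: list with `expected_cost`,
#'   `expected_payoff`, and `severity_distribution` (named probability vector
#'   over the five severity classes).
#' @export
rollback <- function(tree, params) {
  walk <- function(node) {
    cost <- node_cost(node, params)
    if (node$kind == "terminal") {
      sev <- stats::setNames(numeric(5), .severity_classes)
      sev[node$class] <- 1
      return(list(cost = cost, payoff = terminal_payoff(node$class, params),
                  sev = sev))
    }
    p <- vapply(node$branches, function(b) resolve_prob(b$p, params), numeric(1))
    if (any(p < 0 | p > 1))
      stop(sprintf("branch probability outside [0,1] at node '%s'", node$label),
           call. = FALSE)
    if (abs(sum(p) - 1) > 1e-12)
      stop(sprintf("branch probabilities at node '%s' sum to %.15f, not 1",
                   node$label, sum(p)), call. = FALSE)
    acc <- list(cost = cost, payoff = 0,
                sev = stats::setNames(numeric(5), .severity_classes))
    for (i in seq_along(p)) {
      if (p[i] == 0) next  # prune degenerate branches
      sub <- walk(node$branches[[i]]$node)
      acc$cost <- acc$cost + p[i] * sub$cost
      acc$payoff <- acc$payoff + p[i] * sub$payoff
      acc$sev <- acc$sev + p[i] * sub$sev
    }
    acc
  }
  res <- walk(tree)
  structure(list(expected_cost = res$cost, expected_payoff = res$payoff,
                 severity_distribution = res$sev), class = "arm_expectation")
}

#' @export
print.arm_expectation <- function(x, ...) {
  cat(sprintf("<arm_expectation> expected cost £%.2f, expected payoff %.4f\n",
              x$expected_cost, x$expected_payoff))
  print(round(x$severity_distribution, 6))
  invisible(x)
}

#' Map short-run severity classes to the Markov entry distribution
#'
#' Collapses the five severity classes onto the three alive severity levels
#' of the long-run model via the configured class map, spreads each across
#' GOLD stages II-IV by the configured stage mix, and routes short-run deaths
#' to the absorbing dead state. The result is the cycle-0 occupancy vector.
#'
#' @param exp An `arm_expectation`, or a named severity probability vector.
#' @param params A `copd_params` object.
#' @return Named probability vector over the 10 model states.
#' @export
severity_to_entry <- function(exp, params) {
  sev <- if (inherits(exp, "arm_expectation")) exp$severity_distribution else exp
  if (abs(sum(sev) - 1) > 1e-9)
    stop("severity distribution does not sum to 1", call. = FALSE)
  mix <- params$tree$stage_mix
  entry <- stats::setNames(numeric(10), state_space())
  for (cls in setdiff(.severity_classes, "dead")) {
    target <- params$tree$class_state_map[[cls]]
    for (g in 1:3)
      entry[paste0(target, "_", .stages[g])] <-
        entry[paste0(target, "_", .stages[g])] + sev[[cls]] * mix[g]
  }
  entry["dead"] <- sev[["dead"]]
  entry
}

#' List every root-to-leaf pathway of a tree
#'
#' Audit rendering of the tree: one row per pathway with the chain of node
#' labels, the resolved pathway probability, the accumulated cost and the
#' terminal severity class.
#'
#' @param tree Root `tree_node`.
#' @param params A `copd_params` object.
#' @return A `data.frame` with columns `pathway`, `probability`, `cost`,
#'   `class`.
#' @export
tree_pathways <- function(tree, params) {
  rows <- list()
  walk <- function(node, p, cost, labels) {
    cost <- cost + node_cost(node, params)
    labels <- c(labels, node$label)
    if (node$kind == "terminal") {
      rows[[length(rows) + 1L]] <<- data.frame(
        pathway = paste(labels, collapse = " -> "),
        probability = p, cost = cost, class = node$class,
        stringsAsFactors = FALSE)
      return(invisible())
    }
    for (b in node$branches)
      walk(b$node, p * resolve_prob(b$p, params), cost, labels)
  }
  walk(tree, 1, 0, character())
  do.call(rbind, rows)
}
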