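# Independent oracles and fixture builders used across the suite.

default_params <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- load_config()
    cached
  }
})

# --- decision-tree oracle ---------------------------------------------------
# Exhaustive root-to-leaf path enumeration: collects every path's probability,
# accumulated cost and terminal class explicitly, then sums the products.
# Probability references are resolved by a local resolver, independent of the
# package's recursive rollback.

oracle_resolve <- function(ref, params) {
  if (is.numeric(ref)) return(ref)
  if (substr(ref, 1, 1) == "!") return(1 - oracle_resolve(substring(ref, 2), params))
  parts <- strsplit(ref, ".", fixed = TRUE)[[1]]
  if (parts[1] == "tree") params$tree[[parts[2]]]
  else params$probabilities[[parts[1]]][[parts[2]]]$mean
}

oracle_node_cost <- function(node, params) {
  if (is.null(node$cost_items)) return(0)
  total <- 0
  for (item in names(node$cost_items))
    total <- total + node$cost_items[[item]] * params$costs[[item]]$mean
  total
}

oracle_enumerate <- function(tree, params) {
  paths <- list()
  descend <- function(node, p, cost) {
    cost <- cost + oracle_node_cost(node, params)
    if (node$kind == "terminal") {
      paths[[length(paths) + 1L]] <<- list(p = p, cost = cost, class = node$class)
      return(invisible())
    }
    for (b in node$branches)
      descend(b$node, p * oracle_resolve(b$p, params), cost)
  }
  descend(tree, 1, 0)
  classes <- c("mild", "moderate", "severe_full", "severe_partial", "dead")
  sev <- setNames(numeric(5), classes)
  cost <- payoff <- 0
  u_full <- params$utilities$recovery$fully_recovered$mean
  u_part <- params$utilities$recovery$partially_recovered$mean
  for (pt in paths) {
    cost <- cost + pt$p * pt$cost
    sev[pt$class] <- sev[pt$class] + pt$p
    payoff <- payoff + pt$p * switch(pt$class, dead = 0,
                                     severe_partial = u_part, u_full)
  }
  list(expected_cost = cost, expected_payoff = payoff, severity = sev)
}

# Randomly perturbed parameter set for property sweeps (probabilities drawn
# away from bounds so every branch stays resolvable).
random_params <- function(seed) {
  set.seed(seed)
  p <- default_params()
  for (grp in names(p$probabilities))
    for (nm in names(p$probabilities[[grp]]))
      p$probabilities[[grp]][[nm]]$mean <- runif(1, 0.05, 0.95)
  for (nm in names(p$costs))
    p$costs[[nm]]$mean <- p$costs[[nm]]$mean * runif(1, 0.5, 2)
  p$utilities$recovery$fully_recovered$mean <- runif(1, 0.4, 0.9)
  p$utilities$recovery$partially_recovered$mean <- runif(1, 0.2, 0.7)
  p$tree$second_ab_share <- runif(1, 0.1, 0.9)
  p$tree$p_full_given_survival <- runif(1, 0.1, 0.9)
  p
}

# --- cohort oracle ----------------------------------------------------------
# Naive lifetime cohort: builds each cycle's full 10x10 matrix from the raw
# configuration block with nested loops (severity transition x stage
# progression x competing mortality), multiplies occupancy through, and
# accrues discounted increments directly from the definitions.

oracle_cohort <- function(entry, params, state_costs, state_utilities,
                          n_cycles = params$structural$n_cycles) {
  mk <- params$markov
  sc <- params$structural
  mort <- generate_mortality_table(mortality_generator_spec(
    baseline = mk$mortality$baseline, slope = mk$mortality$slope,
    max_age = mk$mortality$max_age))
  S <- rbind(mk$severity_transitions$stable, mk$severity_transitions$mild,
             mk$severity_transitions$moderate)
  prog <- c(mk$stage_progression$stable, mk$stage_progression$mild,
            mk$stage_progression$moderate)
  dd <- rbind(mk$disease_death$stable, mk$disease_death$mild,
              mk$disease_death$moderate)
  occ <- entry
  cost_total <- qaly_total <- 0
  occ_rows <- matrix(0, n_cycles + 1, 10)
  occ_rows[1, ] <- occ
  for (t in 0:(n_cycles - 1)) {
    disc <- (1 + sc$annual_discount_rate)^(-(t + 0.5) * sc$cycle_length_years)
    cost_total <- cost_total + disc * sum(occ * state_costs)
    qaly_total <- qaly_total +
      disc * sum(occ * state_utilities) * sc$cycle_length_years
    age <- floor(sc$start_age + t * sc$cycle_length_years)
    q_annual <- mort$qx[mort$age == age]
    q_ac <- 1 - (1 - q_annual)^sc$cycle_length_years
    M <- matrix(0, 10, 10)
    for (s in 1:3) for (g in 1:3) {
      i <- (s - 1) * 3 + g
      q <- 1 - (1 - q_ac) * (1 - dd[s, g])
      for (s2 in 1:3) for (g2 in 1:3) {
        j <- (s2 - 1) * 3 + g2
        stage_term <- if (g2 == g) (if (g == 3) 1 else 1 - prog[s])
        else if (g2 == g + 1) prog[s] else 0
        M[i, j] <- (1 - q) * S[s, s2] * stage_term
      }
      M[i, 10] <- q
    }
    M[10, 10] <- 1
    occ <- as.vector(occ %*% M)
    occ_rows[t + 2, ] <- occ
  }
  list(cost_total = cost_total, qaly_total = qaly_total, occupancy = occ_rows)
}

# Random but valid long-run configuration for oracle sweeps.
random_markov_params <- function(seed) {
  set.seed(seed)
  p <- default_params()
  p$markov <- generate_transition_defaults(seed = seed, randomize = TRUE)
  p$markov$mortality$baseline <- runif(1, 1e-5, 1e-4)
  p$markov$mortality$slope <- runif(1, 0.05, 0.11)
  for (s in c("stable", "mild", "moderate"))
    p$markov$disease_death[[s]] <- sort(runif(3, 0, 0.03))
  p
}

random_entry <- function(seed) {
  set.seed(seed)
  e <- runif(10)
  e / sum(e)
}

# Write a modified copy of the default YAML config and return its path.
config_variant <- function(edit) {
  raw <- yaml::read_yaml(default_config_path())
  raw <- edit(raw)
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(raw, path, precision = 15)
  path
}
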