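#' Generative description of a stratified closed-cohort population
#'
#' A `population_spec` gives, per confounder stratum, the population size,
#' the prevalence of each exposure level, and the death probability q_x of
#' each level over one closed follow-up interval.  It drives both the
#' deterministic expected-count generator ([expected_counts()]) and the
#' stochastic individual-level sampler ([simulate_pair()]).
#'
#' @param strata list of stratum descriptions; each element is a list with
#'   `id` (text), `N` (population size > 0), `prevalence` (named vector over
#'   all exposure levels, summing to 1), and `qx` (named vector of death
#'   probabilities in \[0,1\], one per level).
#' @param reference name of the reference exposure level.
#' @param label optional text label.
#' @return an object of class `population_spec`.
#' @examples
#' spec <- population_spec(
#'   strata = list(
#'     list(id = "black", N = 1000,
#'          prevalence = c(nonsmoker = 0.65, smoker = 0.35),
#'          qx = c(nonsmoker = 150 / 650, smoker = 0.5))
#'   ),
#'   reference = "nonsmoker"
#' )
#' expected_counts(spec)
#' @export
population_spec <- function(strata, reference, label = NULL) {
  if (length(strata) == 0) stop_data("spec has no strata")
  ids <- vapply(strata, function(s) as.character(s$id), character(1))
  if (anyDuplicated(ids)) stop_data("stratum ids must be unique")
  levels <- names(strata[[1]]$prevalence)
  if (is.null(levels)) stop_data("prevalence vectors must be named by level")
  if (!reference %in% levels) {
    stop_data("reference level '", reference, "' not in prevalence names")
  }
  levels <- c(reference, setdiff(levels, reference))
  strata <- lapply(strata, function(s) {
    if (!setequal(names(s$prevalence), levels) ||
        !setequal(names(s$qx), levels)) {
      stop_data("stratum '", s$id,
                "': prevalence and qx must cover every exposure level")
    }
    pe <- unlist(s$prevalence)[levels]
    qx <- unlist(s$qx)[levels]
    if (any(pe < 0) || abs(sum(pe) - 1) > 1e-8) {
      stop_data("stratum '", s$id, "': prevalences must be >= 0 and sum to 1")
    }
    pe <- pe / sum(pe)  # remove any last-digit slack from file round-trips
    if (any(qx < 0 | qx > 1)) {
      stop_data("stratum '", s$id, "': death probabilities must lie in [0,1]")
    }
    if (is.null(s$N) || s$N <= 0) stop_data("stratum '", s$id, "': N must be > 0")
    list(id = as.character(s$id), N = as.numeric(s$N), prevalence = pe, qx = qx)
  })
  structure(list(strata = strata, levels = levels, reference = reference,
                 label = label),
            class = "population_spec")
}

#' @export
print.population_spec <- function(x, ...) {
  cat("Population spec", if (!is.null(x$label)) paste0(": ", x$label), "\n",
      length(x$strata), " strata, levels: ",
      paste(x$levels, collapse = ", "),
      " (reference: ", x$reference, ")\n", sep = "")
  invisible(x)
}

#' Selection-into-sample mechanism
#'
#' Describes how individuals from the population enter the observed sample.
#' `none` means the sample is the population.  `direct_risk` asserts sample
#' death probabilities directly (the hypothetical-data device: the sample
#' looks like the population except that its exposed members die less often,
#' the footprint of health selection).  `latent_health` is a mechanistic
#' collider model: each individual carries latent health U ~ N(0,1);
#' inclusion in the sample has log-odds a0 + a1 U (+ (a1_exposed - a1) U and
#' + a2, for exposed individuals), and death probability is the stratum/level
#' base q_x shifted on the log-odds scale by b1 U.  When inclusion rises with
#' U, mortality falls with U (b1 < 0), and selection on U is stronger among
#' the exposed (a1_exposed > a1 or a2 != 0), conditioning on inclusion makes
#' sampled exposed members healthier than sampled unexposed ones and the
#' sample RR falls below the population RR — endogenous selection (collider)
#' bias.
#'
#' @param mode `"none"`, `"direct_risk"`, or `"latent_health"`.
#' @param qx (direct_risk) data frame `stratum`, `level`, `qx` of sample
#'   death probabilities; cells not listed keep their population values.
#' @param a0 (latent_health) baseline inclusion log-odds.
#' @param a1 inclusion log-odds slope on U for unexposed individuals.
#' @param a1_exposed slope on U for exposed individuals (default `a1`).
#' @param a2 additive inclusion log-odds for exposed individuals.
#' @param b1 mortality log-odds slope on U (negative: healthier people die
#'   less).
#' @return an object of class `selection_spec`.
#' @export
selection_spec <- function(mode = c("none", "direct_risk", "latent_health"),
                           qx = NULL, a0 = 0, a1 = 1, a1_exposed = NULL,
                           a2 = 0, b1 = -1) {
  mode <- match.arg(mode)
  if (mode == "direct_risk") {
    if (is.null(qx) || !all(c("stratum", "level", "qx") %in% names(qx))) {
      stop_data("direct_risk selection needs qx with columns stratum, level, qx")
    }
    if (any(qx$qx < 0 | qx$qx > 1)) stop_data("sample qx must lie in [0,1]")
  }
  structure(list(mode = mode, qx = qx, a0 = a0, a1 = a1,
                 a1_exposed = a1_exposed %||% a1, a2 = a2, b1 = b1),
            class = "selection_spec")
}

#' Deterministic expected-count cohort from a population spec
#'
#' Each stratum x level cell receives N_i * pe_ik persons, of whom
#' N_i * pe_ik * q_x(k,i) are expected to die; counts are real-valued and
#' conserve N exactly (survived + died = N_i * pe_ik).
#'
#' @param spec a `population_spec`.
#' @param label cohort label (defaults to the spec label).
#' @return a `paf_cohort` with expected (possibly non-integer) counts.
#' @export
expected_counts <- function(spec, label = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  rows <- do.call(rbind, lapply(spec$strata, function(s) {
    n <- s$N * s$prevalence
    died <- n * s$qx
    data.frame(stratum = s$id, level = spec$levels,
               survived = as.numeric(n - died), died = as.numeric(died),
               row.names = NULL)
  }))
  cohort(rows, reference = spec$reference, label = label %||% spec$label)
}

# marginal and inclusion-conditional cell quantities under latent_health,
# by Gauss-Hermite integration over U ~ N(0,1)
latent_health_cells <- function(spec, selection, gh_points = 61) {
  gh <- gauss_hermite_normal(gh_points)
  u <- gh$nodes; w <- gh$weights
  do.call(rbind, lapply(spec$strata, function(s) {
    do.call(rbind, lapply(spec$levels, function(lv) {
      exposed <- as.numeric(lv != spec$reference)
      slope <- if (exposed == 1) selection$a1_exposed else selection$a1
      p_inc <- stats::plogis(selection$a0 + slope * u + selection$a2 * exposed)
      base <- s$qx[[lv]]
      p_die <- if (base %in% c(0, 1)) rep(base, length(u)) else {
        stats::plogis(stats::qlogis(base) + selection$b1 * u)
      }
      n_cell <- s$N * s$prevalence[[lv]]
      data.frame(
        stratum = s$id, level = lv,
        n_pop = n_cell,
        die_pop = n_cell * sum(w * p_die),
        n_sample = n_cell * sum(w * p_inc),
        die_sample = n_cell * sum(w * p_inc * p_die),
        row.names = NULL
      )
    }))
  }))
}

#' Paired population and observed-sample cohorts under a selection mechanism
#'
#' Generates a population cohort and the sample cohort that a survey subject
#' to the given selection mechanism would observe.  In `expected` mode (the
#' default) both cohorts carry deterministic expected counts — under
#' `latent_health` these are exact integrals over the latent-health
#' distribution, so collider bias can be asserted on expectations rather
#' than on noisy draws.  In `stochastic` mode `n` individuals are drawn
#' (stratum by population share, exposure by prevalence, U ~ N(0,1) where
#' relevant), deaths are realized from the mortality model, and inclusion
#' decides membership in the sample; the same seed always reproduces the
#' same pair.
#'
#' @param spec a `population_spec`.
#' @param selection a `selection_spec` (default: no selection).
#' @param mode `"expected"` or `"stochastic"`.
#' @param n number of individuals to draw (stochastic mode).
#' @param seed integer RNG seed (stochastic mode); recorded in the result.
#' @param gh_points quadrature points for latent-health expectations.
#' @return an object of class `simulated_pair`: list with `population` and
#'   `sample` (`paf_cohort`s), `mode`, and `seed`.
#' @export
simulate_pair <- function(spec, selection = selection_spec("none"),
                          mode = c("expected", "stochastic"),
                          n = NULL, seed = NULL, gh_points = 61) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "population_spec"),
            inherits(selection, "selection_spec"))
  if (mode == "expected") {
    pair <- expected_pair(spec, selection, gh_points)
  } else {
    if (is.null(n) || n <= 0) stop_data("stochastic mode needs n > 0")
    if (is.null(seed)) stop_data("stochastic mode needs an integer seed")
    pair <- with_local_seed(seed, stochastic_pair(spec, selection, n))
  }
  structure(list(population = pair$population, sample = pair$sample,
                 mode = mode, seed = seed),
            class = "simulated_pair")
}

#' @export
print.simulated_pair <- function(x, ...) {
  cat("Simulated population/sample pair (mode:", x$mode,
      if (!is.null(x$seed)) paste0(", seed: ", x$seed), ")\n")
  cat("-- population --\n"); print(x$population)
  cat("-- sample --\n"); print(x$sample)
  invisible(x)
}

expected_pair <- function(spec, selection, gh_points) {
  population <- expected_counts(spec, label = "population")
  sample_cohort <- switch(
    selection$mode,
    none = {
      s <- expected_counts(spec, label = "sample")
      s
    },
    direct_risk = {
      sample_spec <- override_qx(spec, selection$qx)
      expected_counts(sample_spec, label = "sample")
    },
    latent_health = {
      cells <- latent_health_cells(spec, selection, gh_points)
      population <- cohort(
        data.frame(stratum = cells$stratum, level = cells$level,
                   survived = cells$n_pop - cells$die_pop,
                   died = cells$die_pop),
        reference = spec$reference, label = "population")
      cohort(
        data.frame(stratum = cells$stratum, level = cells$level,
                   survived = cells$n_sample - cells$die_sample,
                   died = cells$die_sample),
        reference = spec$reference, label = "sample")
    }
  )
  list(population = population, sample = sample_cohort)
}

override_qx <- function(spec, qx_table) {
  strata <- lapply(spec$strata, function(s) {
    for (lv in spec$levels) {
      hit <- qx_table$qx[qx_table$stratum == s$id & qx_table$level == lv]
      if (length(hit) > 1) {
        stop_data("duplicate sample qx for stratum '", s$id, "', level '", lv, "'")
      }
      if (length(hit) == 1) s$qx[[lv]] <- hit
    }
    s
  })
  population_spec(strata, reference = spec$reference, label = spec$label)
}

with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stochastic_pair <- function(spec, selection, n) {
  ids <- vapply(spec$strata, `[[`, character(1), "id")
  sizes <- vapply(spec$strata, `[[`, numeric(1), "N")
  if (all(sizes == 0)) stop_data("no stratum is reachable (all N are zero)")
  stratum_ix <- sample.int(length(ids), n, replace = TRUE,
                           prob = sizes / sum(sizes))
  level <- character(n)
  for (j in seq_along(ids)) {
    in_j <- stratum_ix == j
    if (!any(in_j)) next
    level[in_j] <- sample(spec$levels, sum(in_j), replace = TRUE,
                          prob = spec$strata[[j]]$prevalence)
  }
  base_qx <- mapply(function(j, lv) spec$strata[[j]]$qx[[lv]],
                    stratum_ix, level)
  exposed <- as.numeric(level != spec$reference)

  if (selection$mode == "latent_health") {
    u <- stats::rnorm(n)
    p_die <- ifelse(base_qx %in% c(0, 1), base_qx,
                    stats::plogis(stats::qlogis(base_qx) + selection$b1 * u))
    died <- stats::rbinom(n, 1, p_die)
    slope <- ifelse(exposed == 1, selection$a1_exposed, selection$a1)
    p_inc <- stats::plogis(selection$a0 + slope * u + selection$a2 * exposed)
    included <- stats::rbinom(n, 1, p_inc) == 1
    sample_died <- died[included]
    sample_stratum <- ids[stratum_ix][included]
    sample_level <- level[included]
  } else {
    died <- stats::rbinom(n, 1, base_qx)
    if (selection$mode == "direct_risk") {
      sample_qx <- base_qx
      qt <- selection$qx
      for (r in seq_len(nrow(qt))) {
        hit <- ids[stratum_ix] == qt$stratum[r] & level == qt$level[r]
        sample_qx[hit] <- qt$qx[r]
      }
      sample_died <- stats::rbinom(n, 1, sample_qx)
    } else {
      sample_died <- died
    }
    sample_stratum <- ids[stratum_ix]
    sample_level <- level
  }

  list(
    population = counts_from_individuals(ids[stratum_ix], level, died,
                                          spec, "population"),
    sample = counts_from_individuals(sample_stratum, sample_level,
                                     sample_died, spec, "sample")
  )
}

counts_from_individuals <- function(stratum, level, died, spec, label) {
  grid <- expand.grid(stratum = vapply(spec$strata, `[[`, character(1), "id"),
                      level = spec$levels, stringsAsFactors = FALSE)
  key <- paste(stratum, level, sep = "\r")
  gkey <- paste(grid$stratum, grid$level, sep = "\r")
  grid$died <- as.numeric(tapply(died, factor(key, levels = gkey), sum))
  grid$n <- as.numeric(table(factor(key, levels = gkey)))
  grid$died[is.na(grid$died)] <- 0
  grid$survived <- grid$n - grid$died
  cohort(grid[c("stratum", "level", "survived", "died")],
         reference = spec$reference, label = label)
}

#' Read a population spec from YAML or JSON
#'
#' The file holds `reference`, optional `label`, and a `strata` list whose
#' elements carry `id`, `N`, `prevalence` (map level -> share) and `qx`
#' (map level -> death probability).
#'
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @return a `population_spec`.
#' @export
read_population_spec <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop_data("unsupported spec format (use .yaml/.yml or .json): ", path)
  }
  strata <- lapply(raw$strata, function(s) {
    list(id = s$id, N = s$N, prevalence = unlist(s$prevalence),
         qx = unlist(s$qx))
  })
  population_spec(strata, reference = raw$reference, label = raw$label)
}
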