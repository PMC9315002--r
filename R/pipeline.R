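#' Default pipeline configuration
#'
#' Returns the configuration list understood by [run_pipeline()]. Values can
#' be overridden by a YAML file (`yaml` argument) and/or by `...` overrides
#' (highest precedence).
#'
#' @param yaml optional path to a YAML config file.
#' @param ... named overrides.
#' @return named list (class `pipeline_config`).
#' @export
pipeline_config <- function(yaml = NULL, ...) {
  cfg <- list(
    schema = 1,
    seed = 1L,
    out_dir = "pipeline_out",
    n_tips = 200,
    lambda_signal = 0.5,
    sigma2 = 2.56e-4,
    n_eggs = 30,
    material = list(E = 3e10, nu = 0.3, density = 1031),
    traits_file = NULL,          # CSV: species, log10_C, clutch, attachment, site, structure, passerine
    tree_file = NULL,            # Newick/Nexus
    eggs_file = NULL,            # CSV: species, A_mm, B_mm, thickness_mm, mass_g
    mcmc = list(iterations = 6000, burnin = 1000, thin = 5, prior_mean = 10,
                branch_scale = 0.001, n_stones = 10, iter_per_stone = 800),
    asr = list(iterations = 20000, burnin = 5000, thin = 10, prior_mean = 0.001),
    trend = list(tau = 0.5, n_boot = 200),
    strict = FALSE)
  if (!is.null(yaml)) {
    over <- yaml::read_yaml(yaml)
    cfg <- utils::modifyList(cfg, over)
  }
  dots <- list(...)
  if (length(dots)) cfg <- utils::modifyList(cfg, dots)
  structure(cfg, class = "pipeline_config")
}

#' Validate a trait table against a tree and the category vocabularies
#'
#' Reports (without failing, unless `strict`) species/tip mismatches,
#' category-vocabulary violations, unit sanity for egg geometry (breadth
#' expected smaller than length; thin-shell check) and missing-data counts.
#'
#' @param traits data frame with at least `species`; nest character and
#'   geometry columns are checked when present.
#' @param tree optional `phylo`.
#' @param strict escalate a non-empty report to an error.
#' @return list of class `validation_report` (empty list = clean).
#' @export
validate_inputs <- function(traits, tree = NULL, strict = FALSE) {
  rep <- list()
  traits <- as.data.frame(traits)
  if (!"species" %in% names(traits)) {
    rep$missing_species_column <- TRUE
  } else {
    if (!is.null(tree)) {
      un <- setdiff(traits$species, tree$tip.label)
      if (length(un)) rep$unmatched <- un
      extra <- setdiff(tree$tip.label, traits$species)
      if (length(extra)) rep$tips_without_data <- extra
    }
    for (ch in intersect(names(nest_vocab), names(traits))) {
      bad <- setdiff(stats::na.omit(unique(as.character(traits[[ch]]))),
                     nest_vocab[[ch]])
      if (length(bad)) rep[[paste0("bad_", ch)]] <- bad
    }
    if (all(c("A_mm", "B_mm") %in% names(traits))) {
      swapped <- which(traits$A_mm > traits$B_mm)
      if (length(swapped))
        rep$breadth_exceeds_length <- traits$species[swapped]
    }
    if (all(c("A_mm", "thickness_mm") %in% names(traits))) {
      thick <- which(traits$thickness_mm / traits$A_mm >= 0.1)
      if (length(thick)) rep$not_thin_shell <- traits$species[thick]
    }
    nacnt <- vapply(traits, function(x) sum(is.na(x)), integer(1))
    if (any(nacnt > 0)) rep$missing_counts <- nacnt[nacnt > 0]
  }
  if (strict && length(rep))
    stop("input validation failed: ", paste(names(rep), collapse = ", "))
  structure(rep, class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (!length(x)) cat("validation: clean\n")
  else for (nm in names(x)) cat(nm, ":", paste(utils::head(unlist(x[[nm]]), 10), collapse = ", "), "\n")
  invisible(x)
}

stage_msg <- function(...) message("[shellevo] ", ...)

#' Run the analysis pipeline
#'
#' Orchestrates the stages behind named subcommands: `simulate` (synthetic
#' study + egg geometries), `stiffness` (batch thin-shell solve + C number),
#' `pgls` (per-character, combined and attachment-by-site interaction
#' models), `coevolve` (dependent vs independent models and Bayes factors
#' per nest character), `asr` (Brownian ancestral states), `trend` (quantile
#' regression of C against node depth), or `all`. Each run writes its
#' outputs plus a JSON manifest (inputs, seeds, package version, wall
#' times); rerunning with identical config and seeds reproduces stochastic
#' outputs exactly.
#'
#' @param config a [pipeline_config()] (or list coercible to one).
#' @param stages character vector of stage names, or `"all"`.
#' @return (invisibly) the manifest list.
#' @export
run_pipeline <- function(config = pipeline_config(), stages = "all") {
  cfg <- if (inherits(config, "pipeline_config")) config
         else do.call(pipeline_config, config)
  all_stages <- c("simulate", "stiffness", "pgls", "coevolve", "asr", "trend")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "shellevo",
                   version = as.character(utils::packageVersion("shellevo")),
                   seed = cfg$seed, stages = list(), outputs = character(0))
  t_path <- function(f) file.path(cfg$out_dir, f)
  read_inputs <- function() {
    tree <- if (!is.null(cfg$tree_file)) {
      if (!file.exists(cfg$tree_file)) stop("tree file not found: ", cfg$tree_file)
      parse_newick(file = cfg$tree_file)
    } else if (file.exists(t_path("tree.nwk"))) parse_newick(file = t_path("tree.nwk"))
    else stop("no tree available: run the simulate stage or set tree_file")
    tf <- if (!is.null(cfg$traits_file)) cfg$traits_file else t_path("traits.csv")
    if (!file.exists(tf)) stop("trait table not found: ", tf)
    traits <- utils::read.csv(tf, check.names = FALSE)
    rep <- validate_inputs(traits, tree, strict = cfg$strict)
    list(tree = tree, traits = traits, report = rep)
  }
  run_stage <- function(name, fun) {
    t0 <- proc.time()[3]
    stage_msg("stage ", name, " ...")
    files <- fun()
    manifest$stages[[name]] <<- list(seconds = round(proc.time()[3] - t0, 2),
                                     files = files)
    manifest$outputs <<- c(manifest$outputs, files)
  }

  if ("simulate" %in% stages) run_stage("simulate", function() {
    study <- simulate_study(cfg$n_tips, seed = cfg$seed,
                            lambda_signal = cfg$lambda_signal,
                            sigma2 = cfg$sigma2)
    eggs <- simulate_geometry(cfg$n_eggs, seed = cfg$seed + 10)
    write_newick(study$tree, t_path("tree.nwk"))
    utils::write.csv(study$traits, t_path("traits.csv"), row.names = FALSE)
    utils::write.csv(eggs, t_path("eggs.csv"), row.names = FALSE)
    c(t_path("tree.nwk"), t_path("traits.csv"), t_path("eggs.csv"))
  })

  if ("stiffness" %in% stages) run_stage("stiffness", function() {
    ef <- if (!is.null(cfg$eggs_file)) cfg$eggs_file else t_path("eggs.csv")
    if (!file.exists(ef)) stop("egg geometry table not found: ", ef)
    eggs <- utils::read.csv(ef)
    res <- stiffness_batch(eggs, E = cfg$material$E, nu = cfg$material$nu,
                           density = cfg$material$density)
    utils::write.csv(res, t_path("stiffness.csv"), row.names = FALSE)
    t_path("stiffness.csv")
  })

  if ("pgls" %in% stages) run_stage("pgls", function() {
    inp <- read_inputs()
    traits <- inp$traits; tree <- inp$tree
    y <- stats::setNames(traits$log10_C, traits$species)
    out <- list()
    for (ch in c("attachment", "site", "structure")) {
      f <- factor(traits[[ch]], levels = nest_vocab[[ch]])
      X <- stats::model.matrix(~f)
      colnames(X) <- c("(Intercept)", paste0(ch, ":", levels(f)[-1]))
      X <- cbind(X, clutch = traits$clutch)
      rownames(X) <- traits$species
      fit <- fit_pgls(y, X, tree)
      out[[ch]] <- list(lambda = fit$lambda, logLik = fit$logLik,
                        AICc = fit$AICc,
                        coefficients = cbind(term = rownames(fit$coefficients),
                                             fit$coefficients))
    }
    # combined model with all three characters
    Xc <- stats::model.matrix(~ attachment + site + structure,
                              data.frame(lapply(traits[c("attachment", "site", "structure")],
                                                function(v) factor(v))))
    Xc <- cbind(Xc, clutch = traits$clutch)
    rownames(Xc) <- traits$species
    fitc <- fit_pgls(y, Xc, tree)
    out$combined <- list(lambda = fitc$lambda, AICc = fitc$AICc,
                         coefficients = cbind(term = rownames(fitc$coefficients),
                                              fitc$coefficients))
    # attachment x site interaction on aggregated binary categories
    att2 <- factor(ifelse(traits$attachment == "basal", "basal", "non-basal"))
    site2 <- factor(ifelse(traits$site == "non-tree vegetation",
                           "non-tree vegetation", "others"))
    Xi <- stats::model.matrix(~ att2 * site2)
    Xi <- cbind(Xi, clutch = traits$clutch)
    rownames(Xi) <- traits$species
    fiti <- fit_pgls(y, Xi, tree)
    out$interaction <- list(lambda = fiti$lambda, AICc = fiti$AICc,
                            coefficients = cbind(term = rownames(fiti$coefficients),
                                                 fiti$coefficients))
    jsonlite::write_json(out, t_path("pgls.json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
    t_path("pgls.json")
  })

  if ("coevolve" %in% stages) run_stage("coevolve", function() {
    inp <- read_inputs()
    traits <- inp$traits; tree <- inp$tree
    cclass <- binarize_c(traits$log10_C)
    binmap <- list(
      attachment = traits$attachment != "basal",
      site = traits$site %in% c("tree", "non-tree vegetation"),
      structure = traits$structure != "scrape/platform")
    out <- list()
    for (ch in names(binmap)) {
      st <- pair_states(stats::setNames(cclass == "high", traits$species),
                        binmap[[ch]])
      cfgm <- mcmc_config(iterations = cfg$mcmc$iterations,
                          burnin = cfg$mcmc$burnin, thin = cfg$mcmc$thin,
                          prior_mean = cfg$mcmc$prior_mean,
                          branch_scale = cfg$mcmc$branch_scale,
                          seed = cfg$seed + match(ch, names(binmap)))
      post <- mcmc_coevolution(tree, st, "dependent", cfgm)
      ml_dep <- marginal_likelihood(tree, st, "dependent", cfgm,
                                    n_stones = cfg$mcmc$n_stones,
                                    iter_per_stone = cfg$mcmc$iter_per_stone)
      ml_ind <- marginal_likelihood(tree, st, "independent", cfgm,
                                    n_stones = cfg$mcmc$n_stones,
                                    iter_per_stone = cfg$mcmc$iter_per_stone)
      out[[ch]] <- list(rates = as.list(post$mean_rates),
                        root_probs = post$root_probs,
                        logml_dependent = ml_dep$logml,
                        logml_independent = ml_ind$logml,
                        bayes_factor = bayes_factor(ml_dep, ml_ind))
      utils::write.csv(post$samples,
                       t_path(paste0("coevolution_samples_", ch, ".csv")),
                       row.names = FALSE)
    }
    jsonlite::write_json(out, t_path("coevolution.json"), auto_unbox = TRUE,
                         digits = NA)
    c(t_path("coevolution.json"),
      t_path(paste0("coevolution_samples_", names(binmap), ".csv")))
  })

  if ("asr" %in% stages) run_stage("asr", function() {
    inp <- read_inputs()
    y <- stats::setNames(inp$traits$log10_C, inp$traits$species)
    a <- asr_mcmc(inp$tree, y, iterations = cfg$asr$iterations,
                  burnin = cfg$asr$burnin, thin = cfg$asr$thin,
                  prior_mean = cfg$asr$prior_mean, seed = cfg$seed + 20)
    utils::write.csv(a$nodes, t_path("asr.csv"), row.names = FALSE)
    t_path("asr.csv")
  })

  if ("trend" %in% stages) run_stage("trend", function() {
    inp <- read_inputs()
    if (!file.exists(t_path("asr.csv")))
      stop("trend stage needs asr.csv: run the asr stage first")
    nodes <- utils::read.csv(t_path("asr.csv"))
    y <- stats::setNames(inp$traits$log10_C, inp$traits$species)
    depths <- node_depths(inp$tree)
    vals <- c(unname(y[inp$traits$species]), nodes$median)
    dps <- c(unname(depths[inp$traits$species]), nodes$depth)
    pass <- NULL
    if ("passerine" %in% names(inp$traits)) {
      node_pass <- node_passerine(inp$tree, stats::setNames(inp$traits$passerine,
                                                            inp$traits$species))
      pass <- c(inp$traits$passerine, node_pass)
    }
    tf <- quantile_trend(vals, dps, pass, tau = cfg$trend$tau,
                         n_boot = cfg$trend$n_boot, seed = cfg$seed + 30)
    out <- list(tau = tf$tau, n = tf$n,
                coefficients = cbind(term = rownames(tf$coefficients),
                                     tf$coefficients))
    jsonlite::write_json(out, t_path("trend.json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
    t_path("trend.json")
  })

  jsonlite::write_json(manifest, t_path("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  stage_msg("done; manifest at ", t_path("manifest.json"))
  invisible(manifest)
}

#' Passerine status of internal nodes
#'
#' A node counts as passerine when all its descendant tips are.
#'
#' @param tree rooted `phylo`.
#' @param tip_flags named logical vector per tip.
#' @return logical vector over internal nodes (ape order).
#' @export
node_passerine <- function(tree, tip_flags) {
  ntip <- length(tree$tip.label)
  desc <- node_descendants(tree)
  vapply((ntip + 1):(ntip + tree$Nnode), function(nd)
    all(tip_flags[tree$tip.label[desc[[nd]]]]), logical(1))
}
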