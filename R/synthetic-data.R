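#' Configuration for the synthetic dual-profiling generator
#'
#' Defines the simulated study: two tumour-subtype classes of unequal size
#' (defaults mirror a 15 basal-like / 41 luminal-A cohort), a miRNA panel with
#' planted hub/module correlation structure, target mRNAs linearly coupled to
#' their regulating miRNAs, and exponential survival times with an optional
#' class-dependent hazard.
#'
#' Each planted module consists of one hub miRNA and `module_size` partner
#' miRNAs. The hub itself is the module's shared standard-normal latent
#' factor; each partner loads `rho` on it (partner = rho * hub +
#' sqrt(1 - rho^2) * noise, unit marginal variance). Hub--partner correlation
#' is therefore `rho` and partner--partner correlation `rho^2`, which is what
#' lets data-processing-inequality pruning collapse each module to a
#' hub-centred star and makes the planted hubs topologically recoverable.
#'
#' @param n_class_a,n_class_b samples in the two classes (class A listed
#'   first; defaults 15 and 41).
#' @param n_mirna total miRNAs on the panel.
#' @param n_hubs planted hub miRNAs.
#' @param module_size correlated partner miRNAs per hub.
#' @param rho partner loading on the module factor, in `[0, 1)`.
#' @param de_fraction fraction of miRNAs given a class mean shift.
#' @param effect_size mean shift in SD units, applied to class-B samples with
#'   a random sign per miRNA.
#' @param n_genes size of the mRNA gene universe.
#' @param targets_per_mirna target genes drawn (without replacement) per miRNA.
#' @param coupling miRNA-to-target linear coefficient; negative by default to
#'   reflect repression. Additive when a gene is targeted by several miRNAs.
#' @param noise_sd residual SD of the mRNA noise.
#' @param hazard_ratio class-B vs class-A hazard for survival times
#'   (1 = no survival difference).
#' @param baseline_hazard class-A exponential event rate per time unit.
#' @param class_names names of the two classes, class A first.
#' @param seed integer RNG seed; identical config + seed gives bit-identical
#'   output.
#' @return an object of class `synthetic_config` (a validated list).
#' @seealso [generate_dual_dataset()]
#' @export
synthetic_config <- function(n_class_a = 15, n_class_b = 41, n_mirna = 200,
                             n_hubs = 10, module_size = 5, rho = 0.9,
                             de_fraction = 0.2, effect_size = 2,
                             n_genes = 2000, targets_per_mirna = 10,
                             coupling = -0.8, noise_sd = 0.5,
                             hazard_ratio = 1, baseline_hazard = 0.1,
                             class_names = c("basal_like", "luminal_A"),
                             seed = 1L) {
  cfg <- list(n_class_a = n_class_a, n_class_b = n_class_b, n_mirna = n_mirna,
              n_hubs = n_hubs, module_size = module_size, rho = rho,
              de_fraction = de_fraction, effect_size = effect_size,
              n_genes = n_genes, targets_per_mirna = targets_per_mirna,
              coupling = coupling, noise_sd = noise_sd,
              hazard_ratio = hazard_ratio, baseline_hazard = baseline_hazard,
              class_names = class_names, seed = as.integer(seed))
  for (f in c("n_class_a", "n_class_b", "n_mirna", "n_hubs", "module_size",
              "n_genes", "targets_per_mirna")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 1 || v != round(v))
      stop_input("invalid config: '%s' must be a positive integer", f)
    cfg[[f]] <- as.integer(v)
  }
  for (f in c("rho", "de_fraction", "effect_size", "coupling", "noise_sd",
              "hazard_ratio", "baseline_hazard")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v))
      stop_input("invalid config: '%s' must be a single number", f)
  }
  if (cfg$rho < 0 || cfg$rho >= 1)
    stop_input("invalid config: 'rho' must be in [0, 1)")
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1)
    stop_input("invalid config: 'de_fraction' must be in [0, 1]")
  if (cfg$noise_sd <= 0)
    stop_input("invalid config: 'noise_sd' must be > 0")
  if (cfg$hazard_ratio <= 0 || cfg$baseline_hazard <= 0)
    stop_input("invalid config: 'hazard_ratio' and 'baseline_hazard' must be > 0")
  if (cfg$n_hubs * (1L + cfg$module_size) > cfg$n_mirna)
    stop_input("invalid config: 'n_hubs' * (1 + 'module_size') exceeds 'n_mirna'")
  if (cfg$targets_per_mirna > cfg$n_genes)
    stop_input("invalid config: 'targets_per_mirna' exceeds 'n_genes'")
  if (length(cfg$class_names) != 2 || anyDuplicated(cfg$class_names))
    stop_input("invalid config: 'class_names' must be 2 distinct names")
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic miRNA/mRNA dual-profiling dataset with planted truth
#'
#' Draws a miRNA expression matrix with planted hub modules and class mean
#' shifts, an mRNA matrix whose targeted genes carry a linear imprint of their
#' regulating miRNAs, a miRNA-to-target map, an exponential survival table
#' censored administratively at the 75th percentile of event times, and the
#' ground-truth record of everything planted.
#'
#' @param config a [synthetic_config()] object.
#' @return a list with elements `mirna` (miRNA x sample matrix, class labels
#'   attached as the `labels` attribute), `mrna` (gene x sample matrix),
#'   `targets` (named list: miRNA -> character vector of gene IDs),
#'   `survival` (data.frame: sample_id, time, event), and `truth` (list:
#'   `hub_ids`, `module_members`, `de_ids` data.frame with direction,
#'   `coupling_map` data.frame).
#' @examples
#' sim <- generate_dual_dataset(synthetic_config(n_mirna = 30, n_hubs = 2,
#'                                               n_genes = 100, seed = 7))
#' dim(sim$mirna)
#' sim$truth$hub_ids
#' @export
generate_dual_dataset <- function(config) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, as.list(config))
  cfg <- config
  n <- cfg$n_class_a + cfg$n_class_b
  sample_ids <- sprintf("S%03d", seq_len(n))
  labels <- stats::setNames(
    rep(cfg$class_names, c(cfg$n_class_a, cfg$n_class_b)), sample_ids)
  mirna_ids <- sprintf("miR-%03d", seq_len(cfg$n_mirna))
  gene_ids <- sprintf("GENE%04d", seq_len(cfg$n_genes))

  with_seed(cfg$seed, {
    ## miRNA layer: independent N(0,1) background, then hub modules
    M <- matrix(rnorm(cfg$n_mirna * n), nrow = cfg$n_mirna,
                dimnames = list(mirna_ids, sample_ids))
    n_module <- cfg$n_hubs * (1L + cfg$module_size)
    module_nodes <- sample(mirna_ids, n_module)
    hub_ids <- module_nodes[seq_len(cfg$n_hubs)]
    members <- matrix(module_nodes[-seq_len(cfg$n_hubs)],
                      nrow = cfg$module_size)
    module_members <- stats::setNames(
      lapply(seq_len(cfg$n_hubs), function(h) sort(members[, h])), hub_ids)
    for (h in seq_len(cfg$n_hubs)) {
      f <- rnorm(n)
      M[hub_ids[h], ] <- f
      for (m in module_members[[h]])
        M[m, ] <- cfg$rho * f + sqrt(1 - cfg$rho^2) * rnorm(n)
    }

    ## class mean shifts
    n_de <- round(cfg$de_fraction * cfg$n_mirna)
    de_ids <- if (n_de > 0) sort(sample(mirna_ids, n_de)) else character(0)
    direction <- if (n_de > 0) sample(c(-1, 1), n_de, replace = TRUE) else numeric(0)
    is_b <- labels == cfg$class_names[2]
    for (i in seq_along(de_ids))
      M[de_ids[i], is_b] <- M[de_ids[i], is_b] + direction[i] * cfg$effect_size

    ## mRNA layer: independent noise plus additive miRNA coupling on targets
    G <- matrix(rnorm(cfg$n_genes * n, sd = cfg$noise_sd), nrow = cfg$n_genes,
                dimnames = list(gene_ids, sample_ids))
    targets <- stats::setNames(vector("list", cfg$n_mirna), mirna_ids)
    for (mid in mirna_ids) {
      tg <- sort(sample(gene_ids, cfg$targets_per_mirna))
      targets[[mid]] <- tg
      G[tg, ] <- G[tg, ] + rep(cfg$coupling * M[mid, ], each = length(tg))
    }
    coupling_map <- data.frame(
      mirna = rep(mirna_ids, lengths(targets)),
      gene = unlist(targets, use.names = FALSE),
      coefficient = cfg$coupling, stringsAsFactors = FALSE)

    ## survival layer: exponential, administrative censoring at 75th pctile
    rate <- ifelse(is_b, cfg$baseline_hazard * cfg$hazard_ratio,
                   cfg$baseline_hazard)
    t_raw <- rexp(n, rate = rate)
    horizon <- quantile(t_raw, 0.75, names = FALSE)
    survival <- data.frame(sample_id = sample_ids,
                           time = pmin(t_raw, horizon),
                           event = as.integer(t_raw <= horizon),
                           stringsAsFactors = FALSE)

    truth <- list(hub_ids = sort(hub_ids), module_members = module_members,
                  de_ids = data.frame(mirna = de_ids, direction = direction,
                                      stringsAsFactors = FALSE),
                  coupling_map = coupling_map)
    attr(M, "labels") <- labels
    list(mirna = M, mrna = G, targets = targets, survival = survival,
         truth = truth, config = cfg)
  })
}

#' Write a generated dataset to a directory as plain-text files
#'
#' Emits the generator's four TSV formats (`mirna.tsv`, `mrna.tsv`,
#' `labels.tsv`, `targets.tsv`, `survival.tsv`) plus the ground truth as
#' `truth.json`.
#'
#' @param sim output of [generate_dual_dataset()].
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_dual_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(sim$mirna, file.path(dir, "mirna.tsv"))
  write_expression(sim$mrna, file.path(dir, "mrna.tsv"))
  write_labels(sample_labels(sim$mirna), file.path(dir, "labels.tsv"))
  write_target_map(sim$targets, file.path(dir, "targets.tsv"))
  write_survival(sim$survival, file.path(dir, "survival.tsv"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
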