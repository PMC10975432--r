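#' Configuration for the synthetic Kca dataset generator
#'
#' The generator emulates the structure of measured cuticle-air partition
#' coefficient compilations: ~106 distinct compounds measured once to five
#' times across ~25 plant species and a few tissue types, for ~255 records
#' in total, with responses on the log10 scale (overall mean near 6.3, SD
#' near 3.1 log units). Responses are produced by a generating linear model
#' on the six descriptors plus two Gaussian noise terms: a compound-level
#' lack-of-fit term (`sigma_between`, default 0.8 log units) and a
#' within-compound replicate term (`sigma_noise`, default 0.3 log units,
#' matching the small cross-species spread seen in measured data). Species
#' labels are exchangeable by default; `species_sd` adds an optional species
#' random intercept.
#'
#' @param n_compounds Number of distinct compounds (default 106).
#' @param target_records Total records; replicate counts (each within
#'   `replicate_range`) are allocated to hit this exactly (default 255).
#' @param n_species Number of pseudo-species labels (default 25).
#' @param replicate_range Min/max replicates per compound (default `c(1, 5)`).
#' @param model Generating [linear_model()] (default
#'   `mlr_preset("averaged")`).
#' @param sigma_between,sigma_noise Noise SDs in log units (defaults 0.8 and
#'   0.3).
#' @param species_sd SD of the optional species random intercept (default 0:
#'   exchangeable labels).
#' @param descriptor_source `"parametric"` (multivariate-normal descriptor
#'   vectors) or `"fixture"` (real descriptors computed from the shipped
#'   SMILES library).
#' @param seed Integer seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_compounds = 106L, target_records = 255L,
                         n_species = 25L, replicate_range = c(1L, 5L),
                         model = mlr_preset("averaged"), sigma_between = 0.8,
                         sigma_noise = 0.3, species_sd = 0,
                         descriptor_source = c("parametric", "fixture"),
                         seed = 1L) {
  descriptor_source <- match.arg(descriptor_source)
  if (n_compounds < 5L) abort("`n_compounds` must be >= 5.")
  if (any(c(sigma_between, sigma_noise, species_sd) < 0)) {
    abort("Noise SDs must be >= 0.")
  }
  if (target_records < n_compounds * replicate_range[1] ||
      target_records > n_compounds * replicate_range[2]) {
    abort("`target_records` unreachable with the given replicate range.")
  }
  structure(
    list(n_compounds = as.integer(n_compounds),
         target_records = as.integer(target_records),
         n_species = as.integer(n_species),
         replicate_range = as.integer(replicate_range),
         model = model, sigma_between = sigma_between,
         sigma_noise = sigma_noise, species_sd = species_sd,
         descriptor_source = descriptor_source, seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Generate a descriptor table for synthetic compounds
#'
#' Parametric mode draws the six descriptors from independent (by default)
#' truncated normal marginals with location/scale chosen to mimic organic
#' pollutants in the modeled property ranges; lead-like scores are snapped
#' to their admissible `m/k` grid. Fixture mode parses the shipped SMILES
#' library (~130 structures: chlorobenzenes, PCB-like biphenyls, PAHs,
#' alkanes, alcohols, esters and relatives) and computes real descriptors
#' via [mol_descriptors()].
#'
#' @param config A [synth_config()].
#' @param correlate Optional correlation to plant between `VE1_L` and
#'   `H_Dz(p)` in parametric mode (e.g. 0.95 to exercise the prefilter);
#'   default 0 (independent columns).
#' @return A descriptor tibble (`compound_id` + the six descriptor columns;
#'   fixture mode also carries `smiles`).
#' @export
generate_descriptors <- function(config = synth_config(), correlate = 0) {
  n <- config$n_compounds
  if (config$descriptor_source == "fixture") {
    path <- system.file("extdata", "fixture_smiles.csv",
                        package = "cuticleqspr")
    if (!nzchar(path) || !file.exists(path)) {
      abort("Fixture SMILES library not found in the installed package.")
    }
    lib <- readr::read_csv(path, show_col_types = FALSE)
    if (n > nrow(lib)) {
      abort(paste0("Fixture library has only ", nrow(lib), " structures."))
    }
    pick <- withr::with_seed(config$seed, sample.int(nrow(lib), n))
    d <- mol_descriptors(lib[sort(pick), ], smiles = smiles, id = compound_id)
    if (nrow(attr(d, "failures"))) {
      abort("Fixture SMILES failed to parse; library is corrupt.")
    }
    return(d)
  }
  withr::with_seed(config$seed, {
    z1 <- rnorm(n); z2 <- rnorm(n)
    zH <- correlate * z1 + sqrt(max(0, 1 - correlate^2)) * z2
    tibble(
      compound_id = sprintf("SYN%03d", seq_len(n)),
      VE1_L = pmax(0.2, 1.9 + 0.35 * z1),
      SpPos_A = pmax(0, 8.9 + 1.4 * rnorm(n)),
      `SpMax2_Bh(v)` = 1.2 + 0.25 * rnorm(n),
      `H_Dz(p)` = pmax(1, 80 + 22 * zH),
      LLS_01 = round(6 * pmin(1, pmax(0, 0.55 + 0.18 * rnorm(n)))) / 6,
      LLS_02 = round(8 * pmin(1, pmax(0, 0.65 + 0.18 * rnorm(n)))) / 8
    )
  })
}

#' Generate a replicate-level synthetic Kca dataset
#'
#' Per compound, the latent value is the generating model's prediction plus
#' compound-level noise `N(0, sigma_between^2)`; each replicate (tagged with
#' a random pseudo-species and tissue) observes the latent value plus
#' `N(0, sigma_noise^2)` (plus the optional species intercept). Replicate
#' counts are allocated to hit `target_records` exactly.
#'
#' @param config A [synth_config()].
#' @param descriptors Optional pre-computed descriptor table (default:
#'   [generate_descriptors()] under `config`).
#' @return A replicate-level tibble (one row per measurement) with
#'   `compound_id`, `species`, `tissue`, the descriptor columns, `log_kca`,
#'   and `log_kca_true` (the noise-free generating prediction). Attribute
#'   `"provenance"` is `"raw"`.
#' @export
generate_kca_dataset <- function(config = synth_config(), descriptors = NULL) {
  desc <- descriptors %||% generate_descriptors(config)
  n <- nrow(desc)
  model <- config$model
  truth <- predict(model, desc)
  withr::with_seed(config$seed + 1L, {
    latent <- truth + rnorm(n, 0, config$sigma_between)
    # replicate counts: start at the minimum, deal out the surplus
    counts <- rep(config$replicate_range[1], n)
    surplus <- config$target_records - sum(counts)
    while (surplus > 0L) {
      open <- which(counts < config$replicate_range[2])
      take <- open[sample.int(length(open), min(surplus, length(open)))]
      counts[take] <- counts[take] + 1L
      surplus <- surplus - length(take)
    }
    species_pool <- sprintf("species_%02d", seq_len(config$n_species))
    species_fx <- rnorm(config$n_species, 0, config$species_sd)
    rows <- desc[rep(seq_len(n), counts), , drop = FALSE]
    idx <- rep(seq_len(n), counts)
    sp <- sample.int(config$n_species, nrow(rows), replace = TRUE)
    rows$species <- species_pool[sp]
    rows$tissue <- sample(c("leaf", "fruit", "stem"), nrow(rows),
                          replace = TRUE)
    rows$log_kca_true <- truth[idx]
    rows$log_kca <- latent[idx] + species_fx[sp] +
      rnorm(nrow(rows), 0, config$sigma_noise)
  })
  attr(rows, "provenance") <- "raw"
  rows
}
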