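# Synthetic multi-kingdom community generator. Emulates the statistical
# structure the network analysis assumes -- compositional counts at fixed
# sequencing depth, planted cross-kingdom correlation modules, designated
# methane-cycling OTUs, three inundation groups, and a CH4 flux linearly
# linked to one planted module's eigengene -- so every downstream stage is
# testable without sequencing data.

methanogen_orders <- function() {
  c("Methanopyrales", "Methanococcales", "Methanobacteriales",
    "Methanomicrobiales", "Methanosarcinales", "Methanocellales",
    "Methanomassiliicoccales")
}

methanotroph_markers <- function() {
  c("Methylococcales", "Methylomirabilales", "Methylacidiphilales",
    "Methylocystis", "Methylosinus", "Methylocella", "Methylocapsa")
}

synth_taxonomy <- function(kingdom, idx) {
  switch(kingdom,
    prokaryote = sprintf(
      "Bacteria;Phylum%02d;Class%02d;Order%03d;Family%03d;Genus%04d",
      idx %% 12 + 1, idx %% 25 + 1, idx, idx, idx),
    fungus = sprintf(
      "Fungi;Ascomycota;Class%02d;Order%03d;Family%03d;Genus%04d",
      idx %% 8 + 1, idx, idx, idx),
    cercozoa = sprintf(
      "Eukaryota;Cercozoa;Class%02d;Order%03d;Family%03d;Genus%04d",
      idx %% 6 + 1, idx, idx, idx)
  )
}

#' Plant the ground truth of a synthetic multi-kingdom community
#'
#' Lays out OTUs across kingdoms, assigns a fraction of them to planted
#' correlation modules (blocks of the latent Spearman structure with
#' within-module correlation `rho_within`, zero between modules), designates
#' methanogen and methanotroph OTUs within the prokaryote pool, draws the
#' per-OTU log-mean abundances (Normal(0, 1), giving a realistic
#' rank-abundance curve), and fixes the module-to-flux linkage used by
#' [simulate_metadata()].
#'
#' Modules are filled by seeded sampling from the pooled OTU list, so they
#' typically span kingdoms, as interdomain modules do.
#'
#' @param n_otus Named integer vector of OTUs per kingdom; names from
#'   `prokaryote`, `fungus`, `cercozoa`.
#' @param n_modules Number of planted modules.
#' @param rho_within Latent within-module correlation, |rho| < 1.
#' @param guild_fractions Named fractions of prokaryote OTUs designated
#'   `methanogen` and `methanotroph`.
#' @param flux_link List with `module` (planted module id driving CH4 flux),
#'   `beta` (link coefficient) and `sigma` (noise sd relative to the
#'   eigengene's sd; `sigma = 0.75` gives a population flux-eigengene
#'   correlation of 0.8).
#' @param module_fraction Fraction of all OTUs assigned to planted modules.
#' @param seed Integer seed; the same seed reproduces the same truth.
#' @return An object of class `synthetic_truth`: list with `otus` (tibble:
#'   `otu_id`, `kingdom`, `taxonomy`, `guild`, `module`, `log_mean`),
#'   `latent_correlation`, `rho_within`, `n_modules`, `flux_link`, `seed`.
#' @export
generate_truth <- function(n_otus = c(prokaryote = 120, fungus = 40,
                                      cercozoa = 40),
                           n_modules = 4,
                           rho_within = 0.9,
                           guild_fractions = c(methanogen = 0.06,
                                               methanotroph = 0.04),
                           flux_link = list(module = 1, beta = 1,
                                            sigma = 0.75),
                           module_fraction = 0.4,
                           seed = 1) {
  stopifnot(abs(rho_within) < 1, n_modules >= 1)
  if (is.null(names(n_otus)) ||
      !all(names(n_otus) %in% c("prokaryote", "fungus", "cercozoa"))) {
    stop("n_otus must be named with kingdoms prokaryote/fungus/cercozoa",
         call. = FALSE)
  }
  p <- sum(n_otus)
  n_planted <- floor(module_fraction * p)
  per_module <- n_planted %/% n_modules
  if (per_module < 3) {
    stop("infeasible block sizes: each planted module needs >= 3 OTUs ",
         "(got ", per_module, "); increase module_fraction or n_otus",
         call. = FALSE)
  }
  prefix <- c(prokaryote = "P", fungus = "F", cercozoa = "C")
  kingdom <- rep(names(n_otus), n_otus)
  within_idx <- unlist(lapply(n_otus, seq_len), use.names = FALSE)
  otu_id <- sprintf("%s%03d", prefix[kingdom], within_idx)

  # per-module kingdom quotas proportional to kingdom sizes, so every
  # planted module spans the kingdoms the way interdomain modules do
  quota <- round(per_module * n_otus / p)
  quota[which.max(n_otus)] <- quota[which.max(n_otus)] +
    (per_module - sum(quota))
  if (any(quota < 0) || any(quota * n_modules > n_otus)) {
    stop("infeasible block sizes: kingdom pools too small for ",
         n_modules, " modules", call. = FALSE)
  }
  with_seed_if(seed, {
    module <- integer(p)
    for (k in names(n_otus)) {
      if (quota[[k]] == 0) next
      pool <- which(kingdom == k)
      picks <- sample(pool, quota[[k]] * n_modules)
      module[picks] <- rep(seq_len(n_modules), each = quota[[k]])
    }

    # methane guilds live in the prokaryote pool
    guild <- rep("none", p)
    prok <- which(kingdom == "prokaryote")
    n_gen <- ceiling(guild_fractions[["methanogen"]] * length(prok))
    n_oxi <- ceiling(guild_fractions[["methanotroph"]] * length(prok))
    if (n_gen + n_oxi > length(prok)) {
      stop("guild fractions exceed the prokaryote pool", call. = FALSE)
    }
    pick <- sample(prok, n_gen + n_oxi)
    guild[pick[seq_len(n_gen)]] <- "methanogen"
    guild[pick[n_gen + seq_len(n_oxi)]] <- "methanotroph"

    log_mean <- rnorm(p)
  })

  taxonomy <- vapply(seq_len(p), function(i) {
    base <- synth_taxonomy(kingdom[i], within_idx[i])
    if (guild[i] == "methanogen") {
      ord <- methanogen_orders()[(within_idx[i] %% length(methanogen_orders())) + 1]
      base <- sprintf("Archaea;Euryarchaeota;Class%02d;%s;Family%03d;Genus%04d",
                      within_idx[i] %% 4 + 1, ord, within_idx[i], within_idx[i])
    } else if (guild[i] == "methanotroph") {
      mk <- methanotroph_markers()[(within_idx[i] %% 3) + 1]
      base <- sprintf("Bacteria;Proteobacteria;Gammaproteobacteria;%s;Family%03d;Genus%04d",
                      mk, within_idx[i], within_idx[i])
    }
    base
  }, character(1))

  sigma <- diag(p)
  for (m in seq_len(n_modules)) {
    idx <- which(module == m)
    sigma[idx, idx] <- rho_within
  }
  diag(sigma) <- 1
  dimnames(sigma) <- list(otu_id, otu_id)

  structure(list(
    otus = tibble::tibble(otu_id = otu_id, kingdom = kingdom,
                          taxonomy = taxonomy, guild = guild,
                          module = module, log_mean = log_mean),
    latent_correlation = sigma,
    rho_within = rho_within,
    n_modules = n_modules,
    flux_link = flux_link,
    seed = seed
  ), class = "synthetic_truth")
}

#' Simulate compositional OTU counts from a planted truth
#'
#' Draws a latent multivariate Gaussian with the planted correlation
#' structure, shifts by the per-OTU log-means and exponentiates to log-normal
#' relative abundances, then multinomially samples each sample down to a
#' fixed sequencing depth per kingdom. Within every kingdom, each sample's
#' counts sum exactly to that kingdom's depth.
#'
#' @param truth A `synthetic_truth` object.
#' @param n_samples Number of samples (>= 4).
#' @param depth Sequencing depth: a single integer, or a vector named by
#'   kingdom.
#' @param seed Integer seed.
#' @return A count table tibble covering all kingdoms (filter on `kingdom`
#'   for per-kingdom tables).
#' @export
simulate_counts <- function(truth, n_samples = 27,
                            depth = c(prokaryote = 50000, fungus = 51591,
                                      cercozoa = 33548),
                            seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"), n_samples >= 4)
  otus <- truth$otus
  kingdoms <- unique(otus$kingdom)
  if (is.null(names(depth))) {
    depth <- setNames(rep_len(depth, length(kingdoms)), kingdoms)
  }
  p <- nrow(otus)
  counts <- matrix(0L, p, n_samples,
                   dimnames = list(otus$otu_id,
                                   sprintf("S%02d", seq_len(n_samples))))
  with_seed_if(seed, {
    z <- MASS::mvrnorm(n_samples, mu = rep(0, p),
                       Sigma = truth$latent_correlation)
    lat <- exp(sweep(z, 2, otus$log_mean, "+"))  # samples x OTUs
    for (k in kingdoms) {
      idx <- which(otus$kingdom == k)
      d <- depth[[k]]
      if (d < length(idx)) {
        warning("depth ", d, " below the number of ", k,
                " OTUs; table will be sparse", call. = FALSE)
      }
      w <- lat[, idx, drop = FALSE]
      w <- w / rowSums(w)
      for (j in seq_len(n_samples)) {
        counts[idx, j] <- rmultinom(1, size = d, prob = w[j, ])
      }
    }
  })
  count_table(counts, taxonomy = otus$taxonomy, kingdom = otus$kingdom,
              guild = otus$guild)
}

# default environmental trait generator: mean, sd, and additive shifts per
# inundation group, loosely shaped like a salt-marsh sediment profile (TP
# higher and oxygen/pH/nitrate lower under deeper inundation).
default_env_spec <- function() {
  list(
    TN = list(mean = 900, sd = 150, shift = c(IL = 0, IM = 0, IH = 0)),
    TP = list(mean = 600, sd = 80, shift = c(IL = 0, IM = 60, IH = 150)),
    ammonium = list(mean = 12, sd = 3, shift = c(IL = 0, IM = 0, IH = 0)),
    nitrate = list(mean = 8, sd = 2, shift = c(IL = 0, IM = -2, IH = -4)),
    organic_matter = list(mean = 3.5, sd = 0.8,
                          shift = c(IL = 0, IM = 0, IH = 0)),
    pH = list(mean = 7.9, sd = 0.2, shift = c(IL = 0, IM = -0.3, IH = -0.2)),
    salinity = list(mean = 6, sd = 1, shift = c(IL = 0, IM = 0, IH = 0)),
    oxygen = list(mean = 15, sd = 3, shift = c(IL = 0, IM = -4, IH = -6))
  )
}

#' Simulate sample metadata linked to the planted community
#'
#' Assigns inundation depths and IL/IM/IH groups by the stated group sizes,
#' draws environmental traits from `env_spec` (normal, with per-group
#' shifts), and sets `ch4_flux = beta * eigengene + Normal(0, sigma * sd(eigengene))`
#' where the eigengene is the flux-linked planted module's eigengene computed
#' from the simulated counts by [module_eigengene()] (one definition, shared
#' with the analysis stage). `mcrA_copies`/`pmoA_copies` are log-normal gene
#' copy numbers positively tied to the flux.
#'
#' @param truth A `synthetic_truth` object.
#' @param counts Count table from [simulate_counts()].
#' @param group_sizes Named sizes of the IL/IM/IH inundation groups; must sum
#'   to the number of samples. The default 7/12/8 mirrors a 27-sample,
#'   three-level inundation design.
#' @param env_spec Trait generator spec (see `default_env_spec()` in the
#'   package source); `NULL` for the defaults.
#' @param seed Integer seed.
#' @return A metadata tibble (`sample_id`, `inundation_depth_cm`, `group`,
#'   the [env_traits()] columns, `ch4_flux`, `mcrA_copies`, `pmoA_copies`).
#' @export
simulate_metadata <- function(truth, counts,
                              group_sizes = c(IL = 7, IM = 12, IH = 8),
                              env_spec = NULL, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  smp <- sample_ids(counts)
  n <- length(smp)
  if (sum(group_sizes) != n) {
    stop("group sizes (", sum(group_sizes), ") must sum to the number of ",
         "samples (", n, ")", call. = FALSE)
  }
  env_spec <- env_spec %||% default_env_spec()
  fl <- truth$flux_link
  if (!fl$module %in% truth$otus$module) {
    stop("flux-linked module ", fl$module, " has no planted OTUs",
         call. = FALSE)
  }
  group <- rep(names(group_sizes), group_sizes)
  depth_pool <- list(IL = c("control", "0"), IM = c("5", "10", "20"),
                     IH = c("30", "40"))
  depth_cm <- unlist(lapply(names(group_sizes), function(g) {
    rep_len(depth_pool[[g]], group_sizes[[g]])
  }), use.names = FALSE)

  partition <- truth$otus[truth$otus$module > 0, c("otu_id", "module")]
  eg <- module_eigengene(counts, partition, fl$module)
  e <- eg$eigengene[smp]

  md <- tibble::tibble(sample_id = smp, inundation_depth_cm = depth_cm,
                       group = group)
  with_seed_if(seed, {
    for (tr in names(env_spec)) {
      sp <- env_spec[[tr]]
      md[[tr]] <- sp$mean + unname(sp$shift[group]) + rnorm(n, 0, sp$sd)
    }
    md$ch4_flux <- fl$beta * unname(e) + rnorm(n, 0, fl$sigma * sd(e))
    fz <- as.numeric(scale(md$ch4_flux))
    md$mcrA_copies <- 10^(7 + 0.3 * fz + rnorm(n, 0, 0.15))
    md$pmoA_copies <- 10^(7 + 0.25 * fz + rnorm(n, 0, 0.2))
  })
  md
}

#' Simulate a complete synthetic study (truth, counts, metadata)
#'
#' Convenience wrapper chaining [generate_truth()], [simulate_counts()] and
#' [simulate_metadata()] with a single master seed (stage seeds are derived
#' deterministically from it).
#'
#' @param n_samples Number of samples.
#' @param depth Sequencing depth (scalar or named by kingdom).
#' @param group_sizes IL/IM/IH group sizes.
#' @param seed Master seed.
#' @param ... Passed to [generate_truth()].
#' @return List with `truth`, `counts`, `metadata`.
#' @export
simulate_community <- function(n_samples = 27,
                               depth = c(prokaryote = 50000, fungus = 51591,
                                         cercozoa = 33548),
                               group_sizes = c(IL = 7, IM = 12, IH = 8),
                               seed = 1, ...) {
  seed <- as.integer(seed)
  truth <- generate_truth(seed = seed, ...)
  counts <- simulate_counts(truth, n_samples = n_samples, depth = depth,
                            seed = seed + 1L)
  metadata <- simulate_metadata(truth, counts, group_sizes = group_sizes,
                                seed = seed + 2L)
  list(truth = truth, counts = counts, metadata = metadata)
}
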