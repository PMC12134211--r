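#' Configuration for the synthetic phenotyping generator
#'
#' Emulates a chloramphenicol-chase experiment in the mother machine: each
#' lineage grows and divides before the medium swap (t = 0), protein
#' synthesis stops at the swap, and total lineage fluorescence then follows a
#' single-exponential maturation model or a double-exponential
#' maturation-plus-bleaching model, with additive Gaussian measurement noise
#' and optional bleed-through from neighbouring traps.
#'
#' @param strains data.frame with columns `strain`, `c`, `alpha`, `tau_m`,
#'   `tau_b` (`NA` for single-exponential strains). `c` is the fluorescence
#'   scale (a.u.), `alpha` the immature/mature ratio at the swap, `tau_m` the
#'   maturation time and `tau_b` the bleaching time (minutes).
#' @param n_lineages_per_strain Lineages simulated per strain.
#' @param t_pre_chl Minutes of imaging before the swap.
#' @param t_post_chl Minutes of imaging after the swap.
#' @param dt_fluor Minutes between fluorescence frames.
#' @param dt_phase Minutes between phase-contrast frames (growth resolution);
#'   `dt_fluor` must be a multiple.
#' @param noise_sd Additive Gaussian noise sd on total lineage fluorescence
#'   (a.u.).
#' @param bleed_fraction Fraction of each trap's fluorescence density that
#'   contaminates its neighbours' surroundings.
#' @param doubling_time Pre-swap area doubling time, minutes.
#' @param growth_stop_tau Time constant (minutes) of the exponential decay of
#'   the growth rate after the swap (chloramphenicol eventually stops growth).
#' @param founder_area_px Founder cell area at birth, pixels.
#' @param bg_per_px Camera background added per pixel of cell area (a.u.).
#' @param seed Integer seed.
#' @return A list of class `pheno_sim_config`.
#' @export
pheno_sim_config <- function(strains,
                             n_lineages_per_strain = 10L,
                             t_pre_chl = 60, t_post_chl = 300,
                             dt_fluor = 5, dt_phase = 1,
                             noise_sd = 0, bleed_fraction = 0,
                             doubling_time = 30, growth_stop_tau = 20,
                             founder_area_px = 100, bg_per_px = 0,
                             seed = 1L) {
  stopifnot(is.data.frame(strains),
            all(c("strain", "c", "alpha", "tau_m", "tau_b") %in%
                  names(strains)))
  if (any(strains$tau_m <= 0)) stop("tau_m must be positive")
  if (any(!is.na(strains$tau_b) & strains$tau_b <= strains$tau_m)) {
    stop("tau_b must exceed tau_m when present")
  }
  if (abs(dt_fluor / dt_phase - round(dt_fluor / dt_phase)) > 1e-9) {
    stop("dt_fluor must be a multiple of dt_phase")
  }
  stopifnot(t_pre_chl >= 0, t_post_chl > 0, noise_sd >= 0,
            bleed_fraction >= 0, bleed_fraction <= 1)
  structure(list(
    strains = strains,
    n_lineages_per_strain = as.integer(n_lineages_per_strain),
    t_pre_chl = t_pre_chl, t_post_chl = t_post_chl,
    dt_fluor = dt_fluor, dt_phase = dt_phase,
    noise_sd = noise_sd, bleed_fraction = bleed_fraction,
    doubling_time = doubling_time, growth_stop_tau = growth_stop_tau,
    founder_area_px = founder_area_px, bg_per_px = bg_per_px,
    seed = as.integer(seed)
  ), class = "pheno_sim_config")
}

#' Evaluate the single-exponential maturation model
#'
#' `F(t) = c (alpha + 1 - alpha exp(-t / tau_m))`: the already-mature pool
#' `c` plus an immature pool `c * alpha` maturing with time constant `tau_m`
#' after synthesis stops at t = 0.
#'
#' @param t Time after the chloramphenicol swap, minutes (`t >= 0`).
#' @param c_ Fluorescence scale (value at t = 0), a.u.
#' @param alpha Immature/mature ratio at the swap.
#' @param tau_m Maturation time, minutes.
#' @return Model fluorescence, a.u.
#' @export
single_exp_value <- function(t, c_, alpha, tau_m) {
  c_ * (alpha + 1 - alpha * exp(-t / tau_m))
}

#' Evaluate the double-exponential maturation-plus-bleaching model
#'
#' `F(t) = c [ (tau_b/(tau_b - tau_m)) (alpha + 1) exp(-t/tau_b)
#'           - alpha (tau_b/(tau_b - tau_m)) exp(-t/tau_m) ]`,
#' where `tau_b > tau_m` is the characteristic bleaching time. As
#' `tau_b -> Inf` this converges to the single-exponential model.
#'
#' @inheritParams single_exp_value
#' @param tau_b Bleaching time, minutes (`tau_b != tau_m`).
#' @return Model fluorescence, a.u.
#' @export
double_exp_value <- function(t, c_, alpha, tau_m, tau_b) {
  if (any(tau_b == tau_m)) stop("tau_b = tau_m makes the model singular")
  r <- tau_b / (tau_b - tau_m)
  c_ * (r * (alpha + 1) * exp(-t / tau_b) - alpha * r * exp(-t / tau_m))
}

.model_value <- function(t, c_, alpha, tau_m, tau_b) {
  if (is.na(tau_b)) single_exp_value(t, c_, alpha, tau_m)
  else double_exp_value(t, c_, alpha, tau_m, tau_b)
}

#' Generate synthetic lineage observations for a chloramphenicol chase
#'
#' Simulates every lineage's cell tree at phase-contrast resolution
#' (exponential area growth, symmetric division when a cell doubles its birth
#' area, growth rate decaying after the swap) and emits cell observations at
#' fluorescence frames. Total lineage fluorescence is the strain's maturation
#' model plus noise (pre-swap frames sit on the model's t = 0 plateau);
#' fluorescence and area are partitioned among the living descendants
#' proportionally to area, so lineage totals are conserved exactly at
#' divisions. Traps are laid out on a line; each trap's surroundings density
#' is `bleed_fraction` times the mean density of its two neighbours.
#'
#' @param config A [pheno_sim_config()].
#' @return A list with:
#'   \describe{
#'     \item{observations}{data.frame `(time, trap_id, lineage_id, cell_id,
#'       parent_id, area, raw_total_intensity, surroundings_mean_density)`;
#'       `time` is minutes relative to the swap;
#'       `raw_total_intensity` includes `bg_per_px * area` of camera
#'       background.}
#'     \item{truth}{data.frame mapping `lineage_id`/`trap_id` to `strain` and
#'       the kinetic parameters.}
#'     \item{config}{echo.}
#'   }
#' @export
gen_phenotyping <- function(config) {
  stopifnot(inherits(config, "pheno_sim_config"))
  set.seed(config$seed)
  strains <- config$strains
  n_lin <- nrow(strains) * config$n_lineages_per_strain

  times <- seq(-config$t_pre_chl, config$t_post_chl, by = config$dt_fluor)
  strain_of <- rep(seq_len(nrow(strains)), each = config$n_lineages_per_strain)
  lineage_id <- sprintf("lin%04d", seq_len(n_lin))
  trap_id <- sprintf("ptrap%04d", seq_len(n_lin))

  obs <- vector("list", n_lin)
  model_mat <- matrix(0, n_lin, length(times))  # noiseless totals for bleed
  for (i in seq_len(n_lin)) {
    s <- strains[strain_of[i], ]
    tree <- .simulate_cell_tree(config, times)
    # fluorescence is continuous at the swap: the pre-swap plateau sits at
    # the model's t = 0 value (c for the single model, c*tau_b/(tau_b-tau_m)
    # for the bleaching model)
    plateau <- .model_value(0, s$c, s$alpha, s$tau_m, s$tau_b)
    total_model <- ifelse(times < 0, plateau,
                          .model_value(pmax(times, 0), s$c, s$alpha,
                                       s$tau_m, s$tau_b))
    total_noisy <- total_model + stats::rnorm(length(times), 0, config$noise_sd)
    model_mat[i, ] <- total_model

    share <- tree$area / tree$total_area
    fl <- share * total_noisy[match(tree$time, times)]
    obs[[i]] <- data.frame(
      time = tree$time, trap_id = trap_id[i], lineage_id = lineage_id[i],
      cell_id = paste0(lineage_id[i], "_", tree$cell_id),
      parent_id = ifelse(is.na(tree$parent_id), NA_character_,
                         paste0(lineage_id[i], "_", tree$parent_id)),
      area = tree$area,
      raw_total_intensity = fl + config$bg_per_px * tree$area,
      stringsAsFactors = FALSE
    )
  }
  observations <- do.call(rbind, obs)

  # surroundings density: bleed from the two linear neighbours
  area_tot <- tapply(observations$area,
                     list(factor(observations$lineage_id, levels = lineage_id),
                          factor(observations$time, levels = times)), sum)
  dens <- model_mat / unclass(area_tot)
  left <- rbind(NA, dens[-n_lin, , drop = FALSE])
  right <- rbind(dens[-1, , drop = FALSE], NA)
  neigh <- (ifelse(is.na(left), 0, left) + ifelse(is.na(right), 0, right)) /
    pmax(1, (!is.na(left)) + (!is.na(right)))
  surr <- config$bleed_fraction * neigh
  li <- match(observations$lineage_id, lineage_id)
  ti <- match(observations$time, times)
  observations$surroundings_mean_density <- surr[cbind(li, ti)]

  truth <- data.frame(
    lineage_id = lineage_id, trap_id = trap_id,
    strain = strains$strain[strain_of],
    c = strains$c[strain_of], alpha = strains$alpha[strain_of],
    tau_m = strains$tau_m[strain_of], tau_b = strains$tau_b[strain_of],
    stringsAsFactors = FALSE
  )
  list(observations = observations, truth = truth, config = config)
}

# Cell tree of one lineage at fluorescence frames. Areas grow exponentially
# at rate log(2)/doubling_time, modulated after the swap by
# exp(-t/growth_stop_tau); a cell divides symmetrically when it reaches twice
# its birth area. Returns one row per (cell alive, frame).
.simulate_cell_tree <- function(config, times) {
  g0 <- log(2) / config$doubling_time
  # integrated growth: area(t) = area(t0) * exp(G(t) - G(t0))
  Gfun <- function(t) {
    ifelse(t <= 0, g0 * t,
           g0 * config$growth_stop_tau * (1 - exp(-t / config$growth_stop_tau)))
  }
  tgrid <- seq(min(times), max(times), by = config$dt_phase)
  G <- Gfun(tgrid)

  # all cells share the same relative growth, so track total lineage area and
  # the division times; divisions are synchronous (symmetric splits)
  a0 <- config$founder_area_px
  total_area_grid <- a0 * exp(G - G[1])
  # generation k when total area in [a0*2^k, a0*2^(k+1)): every doubling of
  # the total splits every cell
  generation <- pmax(0L, floor(log2(total_area_grid / a0)))
  n_cells_grid <- 2L^generation

  keep <- match(times, tgrid)
  rows <- vector("list", length(times))
  for (j in seq_along(times)) {
    k <- keep[j]
    n_cells <- n_cells_grid[k]
    gen <- generation[k]
    cell_ids <- paste0("g", gen, "c", seq_len(n_cells))
    parent_ids <- if (gen == 0L) NA_character_ else {
      paste0("g", gen - 1L, "c", ((seq_len(n_cells) - 1L) %/% 2L) + 1L)
    }
    rows[[j]] <- data.frame(
      time = times[j], cell_id = cell_ids, parent_id = parent_ids,
      area = total_area_grid[k] / n_cells,
      total_area = total_area_grid[k], stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Write lineage observations to CSV
#'
#' @param observations The `observations` element of [gen_phenotyping()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_observations_csv <- function(observations, path) {
  utils::write.csv(observations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read lineage observations from CSV
#'
#' @param path CSV written by [write_observations_csv()] or any external
#'   segmentation/tracking export with the same header.
#' @return data.frame of cell observations.
#' @export
read_observations_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
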