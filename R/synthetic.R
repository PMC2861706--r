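# Seeded synthetic-data generators. Each generator draws from a named figure
# preset whose parameters are the published anchor numbers (pulldown
# fractions, removal percentages, sensitivity folds, TRF endpoints), emits
# tables in the exact shape the quantification modules consume, and attaches
# its own truth parameters so recovery tests never have to re-derive them.
# Densitometry noise is multiplicative log-normal (error proportional to
# signal), mean 1, relative SD `noise`; 10% is the default working value.

#' Named figure presets for the synthetic-data generators
#'
#' Each preset fixes the generator truth for one experiment family:
#' \describe{
#'   \item{fig1b}{Dose-linear pulldown, doses 0-20 J/m^2, three regions
#'     anchored at 20 J/m^2 (telomere 14%, p53 2%, 28S 2%).}
#'   \item{fig2}{Region pulldown fractions at 20 J/m^2: telomere 0.14,
#'     p53 0.02, 28S 0.02.}
#'   \item{fig2_strands}{Strand-restricted telomere pulldown at 20 J/m^2:
#'     C-rich (CCCTAA) strand 0.16, G-rich (TTAGGG) strand 0.06.}
#'   \item{fig3}{102-mer dot blot at 100 and 500 J/m^2; per-site sensitivity
#'     multipliers telomere:repeat:equi = 5:3:1; per-site yield anchored at
#'     0.1 CPD per 40-site oligo at 100 J/m^2.}
#'   \item{fig4}{Repeat-length series at 250 J/m^2; excess over the linear
#'     baseline 1 up to 4 repeats, 3 at 5 repeats, 4.5 from 7 repeats
#'     (interpolated at 6).}
#'   \item{fig5}{Repair time courses at 0-48 h, removal at 48 h: p53 70%,
#'     28S 40%, mtDNA 10%, telomere 10% (exponential removal rates).}
#'   \item{fig6}{TRF lanes: mean TRF 12 kb at passage 12 and 8 kb at passage
#'     28, identical across UVB doses 0-200 J/m^2.}
#' }
#'
#' @param name Preset name.
#' @return An object of class `figure_preset`: list with `name`, `params` and
#'   `provenance` (a note per parameter saying which published quantity it
#'   encodes).
#' @export
figure_preset <- function(name = c(
                            "fig1b", "fig2", "fig2_strands",
                            "fig3", "fig4", "fig5", "fig6"
                          )) {
  name <- match.arg(name)
  p <- switch(name,
    fig1b = list(
      params = list(
        doses = c(0, 5, 10, 15, 20),
        frac_at_20 = c(telomere = 0.14, p53 = 0.02, s28 = 0.02),
        noise = 0.05
      ),
      provenance = c(
        frac_at_20 = "region pulldown fractions at 20 J/m^2 (14% / ~2% / ~2%)",
        doses = "low, minimally-lethal UVC dose range; anchors 0 and 20 J/m^2",
        noise = "working value; replicate scatter is not published"
      )
    ),
    fig2 = list(
      params = list(
        dose = 20,
        fractions = c(telomere = 0.14, p53 = 0.02, s28 = 0.02),
        noise = 0.10
      ),
      provenance = c(
        fractions = "14% telomeric vs ~2% p53 / 28S fragments damaged at 20 J/m^2",
        noise = "working value; replicate scatter is not published"
      )
    ),
    fig2_strands = list(
      params = list(
        dose = 20,
        fractions = c(telomere_CCCTAA = 0.16, telomere_TTAGGG = 0.06),
        noise = 0.10
      ),
      provenance = c(
        fractions = "16% of C-rich and 6% of G-rich strand fragments damaged at 20 J/m^2"
      )
    ),
    fig3 = list(
      params = list(
        doses = c(100, 500),
        oligos = c("Telomere", "Repeat", "Equi-diPyr #1", "Equi-diPyr #2"),
        multipliers = c(5, 3, 1, 1),
        base_yield = 0.1 / (40 * 100),
        noise = 0.10
      ),
      provenance = c(
        multipliers = "telomere 5-fold and arbitrary repeat 3-fold more sensitive than Equi-diPyr",
        base_yield = "0.1-0.5 CPD per 102-mer over 100-500 J/m^2",
        doses = "dot-blot doses 100 and 500 J/m^2"
      )
    ),
    fig4 = list(
      params = list(
        dose = 250,
        telo_repeats = c(2L, 4L, 5L, 6L, 7L, 8L, 10L),
        equi_lengths = c(12, 24, 36, 48, 60),
        excess = c(below5 = 1, at5 = 3, plateau = 4.5),
        noise = 0.10
      ),
      provenance = c(
        excess = "3-fold at 5 repeats, 4-5-fold plateau from 7 repeats; 1 up to 4 repeats",
        dose = "250 J/m^2, about 0.5 CPD per oligo",
        equi_lengths = "Equi designs exist for 12/24/36/48/60-nt tracts only"
      )
    ),
    fig5 = list(
      params = list(
        dose = 10,
        times = c(0, 6, 16, 24, 48),
        initial = c(p53 = 0.01, s28 = 0.01, mtDNA = 0.01, telomere = 0.07),
        removal_48h = c(p53 = 0.70, s28 = 0.40, mtDNA = 0.10, telomere = 0.10),
        noise = 0.10
      ),
      provenance = c(
        removal_48h = "70% / 40% / 10% removed at 48 h; telomere comparable to or below mtDNA",
        dose = "minimally-lethal 10 J/m^2 UVC",
        initial = "only removal ratios are published; levels scaled from the 20 J/m^2 fractions"
      )
    ),
    fig6 = list(
      params = list(
        passages = c(12L, 28L),
        doses = c(0, 10, 50, 100, 200),
        mean_trf_kb = c(`12` = 12, `28` = 8),
        sdlog = 0.25,
        n_replicates = 3L,
        noise = 0.05
      ),
      provenance = c(
        mean_trf_kb = "~12 kb at passage 12, ~8 kb at passage 28, dose-independent",
        doses = "chronic UVB doses 0-200 J/m^2",
        sdlog = "working smear width; lane shape is not published numerically"
      )
    )
  )
  structure(list(name = name, params = p$params, provenance = p$provenance),
    class = "figure_preset"
  )
}

resolve_preset <- function(preset, allowed) {
  if (is.character(preset)) preset <- figure_preset(preset)
  stopifnot(inherits(preset, "figure_preset"))
  if (!preset$name %in% allowed) {
    abort(sprintf(
      "Preset '%s' is not supported here (allowed: %s).",
      preset$name, paste(allowed, collapse = ", ")
    ))
  }
  preset
}

# mean-1 multiplicative log-normal noise with relative SD `scale`
rnoise <- function(n, scale) {
  if (scale == 0) {
    return(rep(1, n))
  }
  sdlog <- sqrt(log(1 + scale^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

GEL_S0 <- 1000
GEL_BG <- 50
GEL_DILUTIONS <- 2^-(0:9)

#' Generate synthetic gel densitometry tables
#'
#' Emulates the measurement tables of the pulldown experiments: for every
#' region/condition/replicate an input dilution series (signal proportional to
#' dilution, i.e. PCR held in its log-linear regime) plus one IP band whose
#' signal corresponds to the preset's true IP/Input fraction, all under
#' multiplicative log-normal noise on a constant film background.
#'
#' @param preset `"fig1b"`, `"fig2"`, `"fig2_strands"` or `"fig5"` (name or
#'   [figure_preset()] object).
#' @param n_replicates Replicates per condition (default 3, triplicate).
#' @param noise Relative noise SD; default the preset's.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A tibble with columns `label`, `region`, `dose`, `time_h`,
#'   `replicate`, `kind` (`"IP"`/`"input_dilution"`), `dilution`, `intensity`,
#'   `background`. The generator truth (per-condition true IP/Input) is in
#'   attribute `"truth"`.
#' @export
generate_gel_signals <- function(preset, n_replicates = 3, noise = NULL, seed = 1L) {
  preset <- resolve_preset(preset, c("fig1b", "fig2", "fig2_strands", "fig5"))
  noise <- noise %||% preset$params$noise
  set.seed(seed)
  truth <- gel_truth_table(preset)
  rows <- truth |>
    dplyr::rowwise() |>
    dplyr::group_split() |>
    purrr::map(function(tr) {
      purrr::map(seq_len(n_replicates), function(rep_i) {
        dil <- GEL_DILUTIONS
        sig_in <- GEL_S0 * dil * rnoise(length(dil), noise)
        sig_ip <- GEL_S0 * tr$true_ip_over_input * rnoise(1, noise)
        tibble(
          label = paste(tr$region, tr$condition, rep_i,
            c(sprintf("d%02d", seq_along(dil)), "IP"),
            sep = "_"
          ),
          region = tr$region,
          dose = tr$dose,
          time_h = tr$time_h,
          replicate = rep_i,
          kind = c(rep("input_dilution", length(dil)), "IP"),
          dilution = c(dil, NA_real_),
          intensity = c(sig_in, if (tr$true_ip_over_input > 0) sig_ip else 0) + GEL_BG,
          background = GEL_BG
        )
      }) |> dplyr::bind_rows()
    }) |>
    dplyr::bind_rows()
  attr(rows, "truth") <- truth
  rows
}

gel_truth_table <- function(preset) {
  p <- preset$params
  if (preset$name == "fig1b") {
    tidyr::expand_grid(
      region = names(p$frac_at_20),
      dose = p$doses
    ) |>
      dplyr::mutate(
        time_h = NA_real_,
        true_ip_over_input = unname(p$frac_at_20[.data$region]) * .data$dose / 20,
        condition = sprintf("D%g", .data$dose)
      )
  } else if (preset$name %in% c("fig2", "fig2_strands")) {
    tibble(
      region = names(p$fractions),
      dose = p$dose,
      time_h = NA_real_,
      true_ip_over_input = unname(p$fractions),
      condition = sprintf("D%g", p$dose)
    )
  } else { # fig5
    rates <- -log(1 - p$removal_48h) / 48
    tidyr::expand_grid(
      region = names(p$initial),
      time_h = p$times
    ) |>
      dplyr::mutate(
        dose = p$dose,
        true_ip_over_input = unname(
          p$initial[.data$region] * exp(-rates[.data$region] * .data$time_h)
        ),
        condition = sprintf("t%g", .data$time_h)
      )
  }
}

DOT_SCALE <- 1000
DOT_BG <- 20

#' Generate synthetic dot-blot grids and repeat-length series
#'
#' For the four-oligo comparison (`fig3`): dot intensities proportional to the
#' expected CPD per 102-mer -- its dipyrimidine site count times the per-site
#' lesion probability under the preset's sensitivity multiplier -- under
#' multiplicative noise. Because the printed Equi-diPyr constructs carry 42
#' dipyrimidine sites against the telomere's 40, the generator's own truth
#' ratio of telomere to Equi signal is slightly below the nominal 5-fold; the
#' emitted truth table records the exact values.
#'
#' For the repeat-length series (`fig4`): Equi signals follow the linear
#' site-count baseline exactly; Telo signals carry the preset's excess factor
#' (1 up to 4 repeats, 3 at 5, 4.5 from 7, interpolated at 6).
#'
#' @param preset `"fig3"` or `"fig4"` (name or [figure_preset()] object).
#' @param n_replicates Replicates (default 3).
#' @param noise Relative noise SD; default the preset's.
#' @param seed Integer seed.
#' @return For `fig3`: a tibble `oligo`, `dose`, `replicate`, `intensity`,
#'   `background` with a `"truth"` attribute (per-dose expected ratios to the
#'   telomere). For `fig4`: a tibble `series` (`"Telo"`/`"Equi"`), `oligo`,
#'   `dipyr_region_length`, `repeat_count`, `dose`, `replicate`, `intensity`,
#'   `background` with a `"truth"` attribute (true excess ratios).
#' @export
generate_dotblot <- function(preset, n_replicates = 3, noise = NULL, seed = 1L) {
  preset <- resolve_preset(preset, c("fig3", "fig4"))
  p <- preset$params
  noise <- noise %||% p$noise
  set.seed(seed)
  if (preset$name == "fig3") {
    sites <- vapply(
      p$oligos,
      function(nm) nrow(enumerate_dipyr_sites(assemble_oligo(nm))),
      integer(1)
    )
    truth <- tidyr::expand_grid(oligo = p$oligos, dose = p$doses) |>
      dplyr::mutate(
        sites = sites[.data$oligo],
        multiplier = setNames(p$multipliers, p$oligos)[.data$oligo],
        expected_cpd = .data$sites *
          (1 - exp(-p$base_yield * .data$multiplier * .data$dose))
      ) |>
      dplyr::group_by(.data$dose) |>
      dplyr::mutate(
        true_ratio_to_telomere =
          .data$expected_cpd / .data$expected_cpd[.data$oligo == "Telomere"]
      ) |>
      dplyr::ungroup()
    out <- tidyr::expand_grid(
      oligo = p$oligos, dose = p$doses,
      replicate = seq_len(n_replicates)
    ) |>
      dplyr::left_join(truth, by = c("oligo", "dose")) |>
      dplyr::mutate(
        intensity = DOT_SCALE * .data$expected_cpd *
          rnoise(dplyr::n(), noise) + DOT_BG,
        background = DOT_BG
      ) |>
      dplyr::select("oligo", "dose", "replicate", "intensity", "background")
    attr(out, "truth") <- truth
    return(out)
  }
  # fig4
  excess_of <- function(n) {
    dplyr::case_when(
      n <= 4 ~ p$excess[["below5"]],
      n == 5 ~ p$excess[["at5"]],
      n == 6 ~ (p$excess[["at5"]] + p$excess[["plateau"]]) / 2,
      TRUE ~ p$excess[["plateau"]]
    )
  }
  telo <- tibble(
    series = "Telo",
    repeat_count = p$telo_repeats,
    dipyr_region_length = 6 * p$telo_repeats
  ) |>
    dplyr::mutate(
      oligo = sprintf("Telo %d", .data$dipyr_region_length),
      true_excess = excess_of(.data$repeat_count)
    )
  equi <- tibble(
    series = "Equi",
    repeat_count = NA_integer_,
    dipyr_region_length = p$equi_lengths
  ) |>
    dplyr::mutate(
      oligo = sprintf("Equi %d", .data$dipyr_region_length),
      true_excess = 1
    )
  truth <- dplyr::bind_rows(telo, equi)
  out <- truth |>
    tidyr::expand_grid(replicate = seq_len(n_replicates)) |>
    dplyr::mutate(
      dose = p$dose,
      intensity = DOT_SCALE * (.data$dipyr_region_length / 12) *
        .data$true_excess * rnoise(dplyr::n(), noise) + DOT_BG,
      background = DOT_BG
    ) |>
    dplyr::select(
      "series", "oligo", "dipyr_region_length", "repeat_count",
      "dose", "replicate", "intensity", "background"
    )
  attr(out, "truth") <- truth
  out
}

#' Generate synthetic TRF lane profiles
#'
#' Builds Southern-blot-like lane profiles for the telomere-shortening
#' experiment: fragment lengths log-normal (smear), migration log-linear in
#' position, a digoxigenin-style marker ladder, constant film background and
#' multiplicative noise. The truth table records, per lane, the generator's
#' own directly-summed `sum(OD)/sum(OD/L)` statistic computed on the
#' noise-free fine profile -- the quantity [bin_lane()] + [mean_trf()] should
#' recover.
#'
#' @param preset `"fig6"` (name or [figure_preset()] object).
#' @param noise Relative noise SD; default the preset's.
#' @param seed Integer seed.
#' @param n_points Fine-profile points per lane (default 300).
#' @return A list with `profiles` (tibble: `lane_id`, `position`,
#'   `intensity`), `ladder` (a [marker_ladder()]), `meta` (tibble: `lane_id`,
#'   `passage`, `dose`, `replicate`) and `truth` (tibble: `lane_id`,
#'   `true_mean_trf_kb`, `target_kb`).
#' @export
generate_trf_lanes <- function(preset = "fig6", noise = NULL, seed = 1L,
                               n_points = 300) {
  preset <- resolve_preset(preset, "fig6")
  p <- preset$params
  noise <- noise %||% p$noise
  set.seed(seed)
  rungs_kb <- c(21.2, 8.6, 7.4, 6.1, 5.0, 4.2, 3.5, 2.8, 2.3, 1.9)
  span <- log(c(max(rungs_kb), min(rungs_kb)) * 1000)
  pos_of <- function(len_bp) (span[1] - log(len_bp)) / (span[1] - span[2])
  ladder <- marker_ladder(pos_of(rungs_kb * 1000), rungs_kb * 1000)
  meta <- tidyr::expand_grid(
    passage = p$passages, dose = p$doses,
    replicate = seq_len(p$n_replicates)
  ) |>
    dplyr::mutate(lane_id = sprintf(
      "P%d_D%g_r%d", .data$passage, .data$dose, .data$replicate
    ))
  x <- seq(0, 1, length.out = n_points)
  log_len <- span[1] - x * (span[1] - span[2])
  lanes <- purrr::pmap(meta, function(passage, dose, replicate, lane_id) {
    target_bp <- p$mean_trf_kb[[as.character(passage)]] * 1000
    mu <- log(target_bp) + p$sdlog^2 / 2
    shape <- stats::dnorm(log_len, mean = mu, sd = p$sdlog)
    true_stat <- (sum(shape) / sum(shape / exp(log_len))) / 1000
    intensity <- shape * rnoise(length(shape), noise) + 0.05
    list(
      profile = tibble(lane_id = lane_id, position = x, intensity = intensity),
      truth = tibble(
        lane_id = lane_id, true_mean_trf_kb = true_stat,
        target_kb = target_bp / 1000
      )
    )
  })
  list(
    profiles = purrr::map(lanes, "profile") |> dplyr::bind_rows(),
    ladder = ladder,
    meta = meta |> dplyr::select("lane_id", "passage", "dose", "replicate"),
    truth = purrr::map(lanes, "truth") |> dplyr::bind_rows()
  )
}
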