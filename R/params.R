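#' Parameters for the perivascular tissue simulator
#'
#' Bundles and validates the parameters of the synthetic tissue generator:
#' vessel geometry, cell placement intensity and the exponential decay of
#' T-cell density with distance from the nearest vessel border.
#'
#' @param image_size_px Integer pair, image width and height in pixels.
#' @param pixel_size_um Pixel edge length in micrometers.
#' @param n_vessels Number of non-overlapping disk vessels to place.
#' @param vessel_radius_um Length-2 numeric, range (min, max) of vessel radii
#'   in micrometers; radii are drawn uniformly from this range.
#' @param baseline_density_per_mm2 Cell intensity at the vessel border
#'   (cells/mm^2), the `rho0` of the intensity `rho0 * exp(-d/lambda)`.
#' @param decay_length_um Decay length `lambda` in micrometers; `Inf`
#'   disables the decay (spatially uniform cells outside vessels).
#' @param marker Marker label assigned to generated cells (`"CD3"` or
#'   `"CD8"`).
#' @param seed Integer seed; the whole realization is a deterministic
#'   function of the parameters and this seed.
#'
#' @details The image must be large enough that the full 180 um annulus ring
#' fits around every vessel; `simulate_tissue()` enforces a placement margin
#' of `vessel_radius + 180 um` from the image edge and errors if the image
#' cannot accommodate it.
#'
#' @return An object of class `spatial_sim_params`.
#' @export
spatial_sim_params <- function(image_size_px = c(1600L, 1600L),
                               pixel_size_um = 0.5,
                               n_vessels = 8L,
                               vessel_radius_um = c(10, 30),
                               baseline_density_per_mm2 = 2000,
                               decay_length_um = 40,
                               marker = c("CD3", "CD8"),
                               seed = 1L) {
  marker <- match.arg(marker)
  stopifnot(
    length(image_size_px) == 2L, all(image_size_px >= 16),
    is.numeric(pixel_size_um), pixel_size_um > 0,
    n_vessels >= 1L,
    length(vessel_radius_um) == 2L, all(vessel_radius_um > 0),
    vessel_radius_um[1] <= vessel_radius_um[2],
    baseline_density_per_mm2 > 0,
    decay_length_um > 0
  )
  structure(list(
    image_size_px = as.integer(image_size_px),
    pixel_size_um = pixel_size_um,
    n_vessels = as.integer(n_vessels),
    vessel_radius_um = as.numeric(vessel_radius_um),
    baseline_density_per_mm2 = baseline_density_per_mm2,
    decay_length_um = decay_length_um,
    marker = marker,
    seed = as.integer(seed)
  ), class = "spatial_sim_params")
}

#' Parameters for the toy transcriptome / variant simulator
#'
#' @param n_transcripts Number of coding sequences to generate.
#' @param cds_length_codons Length-2 integer range of CDS lengths in codons
#'   (including the ATG start and the stop codon).
#' @param n_variants Number of somatic SNVs to plant across the transcripts.
#' @param fraction_synonymous Expected fraction of planted variants that are
#'   synonymous; the remainder are missense.
#' @param fraction_expressed Expected fraction of genes with FPKM > 0.
#' @param hla_alleles Character vector of 4-digit class I alleles
#'   (e.g. `"A*02:01"`).
#' @param seed Integer seed.
#'
#' @return An object of class `genome_sim_params`.
#' @export
genome_sim_params <- function(n_transcripts = 10L,
                              cds_length_codons = c(50L, 200L),
                              n_variants = 10L,
                              fraction_synonymous = 0.3,
                              fraction_expressed = 0.7,
                              hla_alleles = c("A*02:01", "B*07:02", "C*07:01"),
                              seed = 1L) {
  stopifnot(
    n_transcripts >= 1L,
    length(cds_length_codons) == 2L, all(cds_length_codons >= 4L),
    cds_length_codons[1] <= cds_length_codons[2],
    n_variants >= 0L,
    fraction_synonymous >= 0, fraction_synonymous <= 1,
    fraction_expressed >= 0, fraction_expressed <= 1,
    length(hla_alleles) >= 1L
  )
  structure(list(
    n_transcripts = as.integer(n_transcripts),
    cds_length_codons = as.integer(cds_length_codons),
    n_variants = as.integer(n_variants),
    fraction_synonymous = fraction_synonymous,
    fraction_expressed = fraction_expressed,
    hla_alleles = as.character(hla_alleles),
    seed = as.integer(seed)
  ), class = "genome_sim_params")
}

#' Parameters for the TCR repertoire simulator
#'
#' @param n_clones Number of unique CDR3-nt clonotypes.
#' @param frequency_model `"uniform"`, `"geometric"` or `"powerlaw"` clone
#'   frequency distribution.
#' @param model_parameter Success probability `p` for the geometric model,
#'   exponent `alpha` for the power law; ignored for `"uniform"`.
#' @param nonproductive_fraction Expected fraction of clonotypes carrying a
#'   premature stop codon (out-of-frame/stop rearrangements).
#' @param total_reads Total sequencing reads distributed over the clones;
#'   must be at least `n_clones` (each clone retains at least one read).
#' @param seed Integer seed.
#'
#' @return An object of class `repertoire_sim_params`.
#' @export
repertoire_sim_params <- function(n_clones = 50L,
                                  frequency_model = c("uniform", "geometric", "powerlaw"),
                                  model_parameter = 0.1,
                                  nonproductive_fraction = 0.15,
                                  total_reads = 10000L,
                                  seed = 1L) {
  frequency_model <- match.arg(frequency_model)
  stopifnot(
    n_clones >= 1L,
    nonproductive_fraction >= 0, nonproductive_fraction <= 1,
    total_reads >= n_clones
  )
  if (frequency_model == "geometric") {
    stopifnot(model_parameter > 0, model_parameter < 1)
  }
  if (frequency_model == "powerlaw") stopifnot(model_parameter > 0)
  structure(list(
    n_clones = as.integer(n_clones),
    frequency_model = frequency_model,
    model_parameter = model_parameter,
    nonproductive_fraction = nonproductive_fraction,
    total_reads = as.integer(total_reads),
    seed = as.integer(seed)
  ), class = "repertoire_sim_params")
}

#' Parameters for the qPCR Ct table simulator
#'
#' @param genes Character vector of target gene names.
#' @param n_per_group Integer pair: samples in group LGG and group HGG.
#' @param group_delta_ct_shift Per-gene Ct shift (cycles) added to the second
#'   group (HGG); recycled across `genes`. A positive shift lowers the
#'   second group's 2^-dCt expression by `2^-shift`.
#' @param base_delta_ct Baseline target-minus-housekeeping Ct difference
#'   (cycles), recycled across genes.
#' @param ct_noise_sd Gaussian noise SD (cycles) added to every measured Ct.
#' @param housekeeping_ct_mean Mean housekeeping (GAPDH) Ct.
#' @param housekeeping_gene Housekeeping gene name.
#' @param seed Integer seed.
#'
#' @return An object of class `qpcr_sim_params`.
#' @export
qpcr_sim_params <- function(genes = c("CXCL9", "CXCL10", "ICAM1", "GZMK"),
                            n_per_group = c(20L, 20L),
                            group_delta_ct_shift = 0,
                            base_delta_ct = 5,
                            ct_noise_sd = 0.5,
                            housekeeping_ct_mean = 20,
                            housekeeping_gene = "GAPDH",
                            seed = 1L) {
  stopifnot(
    length(genes) >= 1L,
    length(n_per_group) == 2L, all(n_per_group >= 1L),
    ct_noise_sd >= 0,
    housekeeping_ct_mean > 0,
    !housekeeping_gene %in% genes
  )
  structure(list(
    genes = as.character(genes),
    n_per_group = as.integer(n_per_group),
    group_delta_ct_shift = rep_len(group_delta_ct_shift, length(genes)),
    base_delta_ct = rep_len(base_delta_ct, length(genes)),
    ct_noise_sd = ct_noise_sd,
    housekeeping_ct_mean = housekeeping_ct_mean,
    housekeeping_gene = housekeeping_gene,
    seed = as.integer(seed)
  ), class = "qpcr_sim_params")
}
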