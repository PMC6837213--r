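# Shipped reference inputs for the mustelid study system.
#
# The locomotor-type table lists the 29 sampled species with their a-priori
# habit assignments (7 fossorial, 9 generalized, 6 natatorial, 7 scansorial).
# The published timetree is an external input that cannot be redistributed
# here; the package ships a SYNTHETIC stand-in topology that follows current
# musteloid systematics (Taxidiinae basal, then Mellivorinae, Melinae,
# Helictidinae, Guloninae, and Ictonychinae sister to Lutrinae+Mustelinae),
# with Grafen-style synthetic branch lengths.  Topology-only quantities
# (parsimony steps, retention index) are meaningful on it; absolute
# branch-length-dependent results are not.

#' Locomotor-type assignments of the 29 sampled mustelid species
#' @return Data frame with columns `species` and `habit`.
#' @export
mustelid_habits <- function() {
  read.csv(system.file("extdata", "mustelid_locomotor_types.csv",
                       package = "musteloTrab"), stringsAsFactors = FALSE)
}

#' Synthetic stand-in timetree for the sampled mustelids
#'
#' A 29-tip topology consistent with accepted musteloid systematics, given
#' Grafen branch lengths rescaled to `height` (default 16.5, a plausible
#' crown age in Ma).  This is a synthetic stand-in, not the published
#' timetree: use it for topology-dependent quantities only.
#'
#' @param height tree height after rescaling.
#' @return Ultrametric `phylo` object.
#' @export
mustelid_tree <- function(height = 16.5) {
  tr <- ape::read.tree(system.file("extdata", "mustelid_topology_synthetic.nwk",
                                   package = "musteloTrab"))
  tr <- ape::compute.brlen(tr, method = "Grafen")
  h <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * height / h
  tr
}

#' Run the full comparative pipeline on a metrics table
#'
#' For every VOI type: estimates BMsp from TV, runs the size screen and
#' AN(C)OVA routing for each requested parameter with pairwise contrasts;
#' then computes inter-limb ratios, per-type descriptive statistics, a
#' phylogenetic PCA over all VOI parameters plus BMsp, and the two-block
#' PLS between locomotor types and the phylogeny.
#'
#' @param metrics per-specimen, per-VOI parameter table (as written by
#'   [trabecular_metrics()] / [make_synthetic_study()]).
#' @param specimens specimen table (`specimen_id`, `species`, `habit`).
#' @param species_mass named vector (or data frame `species`, `mass_g`).
#' @param tree timetree containing all species.
#' @param parameters parameter columns to analyse.
#' @param alpha,n_perm,seed analysis settings.
#' @return List with `anova` (per VOI x parameter [size_screen()] results),
#'   `bmsp`, `ratios`, `descriptives`, `ppca`, `pls`.
#' @export
run_comparative_study <- function(metrics, specimens, species_mass, tree,
                                  parameters = c("DA", "ConnD", "BVTV",
                                                 "TbTh", "TbSp", "BS"),
                                  alpha = 0.05, n_perm = 999L, seed = 1L) {
  if (is.data.frame(species_mass))
    species_mass <- setNames(species_mass$mass_g, species_mass$species)
  metrics <- merge(metrics, specimens[, c("specimen_id", "habit")],
                   by = "specimen_id")
  voi_types <- unique(metrics$voi_type)
  anova_res <- list(); bmsp_all <- list()
  for (vt in voi_types) {
    sub <- metrics[metrics$voi_type == vt, , drop = FALSE]
    bm <- estimate_specimen_mass(sub$TV, sub$species, species_mass, tree)
    bmsp_all[[vt]] <- data.frame(specimen_id = sub$specimen_id, voi_type = vt,
                                 BMsp = as.numeric(bm))
    for (p in parameters) {
      key <- paste(vt, p, sep = ".")
      anova_res[[key]] <- size_screen(sub[[p]], as.numeric(bm), sub$habit,
                                      sub$species, tree, alpha = alpha,
                                      n_perm = n_perm, seed = seed)
    }
  }
  ratios <- interlimb_ratios(metrics, parameters)
  desc <- list()
  for (vt in voi_types) {
    sub <- metrics[metrics$voi_type == vt, , drop = FALSE]
    for (p in parameters)
      desc[[paste(vt, p, sep = ".")]] <- descriptive_stats(sub[[p]], sub$habit)
  }
  # species-level matrix for the pPCA: parameters per VOI plus BMsp
  sp <- sort(unique(metrics$species))
  cols <- list()
  for (vt in voi_types) {
    sub <- metrics[metrics$voi_type == vt, , drop = FALSE]
    for (p in parameters)
      cols[[paste(vt, p, sep = ".")]] <-
        tapply(sub[[p]], sub$species, mean)[sp]
  }
  bm_df <- do.call(rbind, bmsp_all)
  bm_df <- merge(bm_df, specimens[, c("specimen_id", "species")], by = "specimen_id")
  cols[["BMsp"]] <- tapply(bm_df$BMsp, bm_df$species, mean)[sp]
  X <- do.call(cbind, cols)
  rownames(X) <- sp
  tr_used <- ape::drop.tip(tree, setdiff(tree$tip.label, sp))
  ppca <- phylogenetic_pca(X, tr_used)

  habit_sp <- vapply(sp, function(s)
    specimens$habit[match(s, specimens$species)], character(1))
  pls <- phylo_two_block_pls(dummy_code(setNames(habit_sp, sp)),
                             phylo_block(tr_used), tr_used,
                             n_perm = n_perm, seed = seed)
  list(anova = anova_res, bmsp = do.call(rbind, bmsp_all), ratios = ratios,
       descriptives = desc, ppca = ppca, pls = pls)
}
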