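# End-to-end workflows: activation analysis, pharmacophore consensus, and
# fixture simulation, each writing a reproducible output bundle with a
# manifest (inputs, config, seed, package version).

.stage <- function(outdir, name, expr) {
  ok <- FALSE
  on.exit(if (!ok) {
    unlink(list.files(outdir, full.names = TRUE))
    stopf("pipeline stage '%s' failed", name)
  })
  message(sprintf("[%s] ...", name))
  val <- force(expr)
  ok <- TRUE
  on.exit()
  val
}

.write_manifest <- function(outdir, workflow, config) {
  man <- list(workflow = workflow, config = config,
              package = "gpcrtraj",
              version = as.character(utils::packageVersion("gpcrtraj")))
  jsonlite::write_json(man, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the activation-analysis workflow
#'
#' Computes, for a receptor-chemokine trajectory: per-TM rotation series vs
#' the reference frame, arginine-cage presence, contact records and
#' time-table between the two chains, COM distance series, GROMOS
#' conformational clusters of the receptor, and a Ramachandran summary.
#' Writes rotation_series.csv, arginine_cage.csv, contacts.csv,
#' contact_timetable.csv, com_distance.csv, clusters.json, ramachandran.csv
#' and manifest.json into `outdir`.
#'
#' @param traj a `Trajectory` or path to a multi-MODEL PDB
#' @param receptor_chain,ligand_chain chain ids
#' @param outdir output directory (created)
#' @param segments a `TMSegmentSet` (default [tm_segments_default()] on the
#'   receptor chain)
#' @param criteria an [interaction_criteria()] object
#' @param cage_resids the two residue numbers of the Asp-Arg pair (default
#'   148, 149)
#' @param cluster_cutoff GROMOS cutoff in nm (default 0.2, a published
#'   preset; 0.4 / 0.51 / 0.6 nm are the other presets)
#' @param stride frame stride for the contact analyses
#' @return invisibly, a list with every computed object
#' @export
run_activation <- function(traj, receptor_chain = "R", ligand_chain = "Q",
                           outdir, segments = NULL,
                           criteria = interaction_criteria(),
                           cage_resids = c(148, 149),
                           cluster_cutoff = 0.2, stride = 1) {
  if (is.character(traj)) traj <- read_pdb(traj)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(segments)) segments <- tm_segments_default(chain = receptor_chain)
  chains <- unique(traj$atoms$chain)
  if (!receptor_chain %in% chains)
    stopf("receptor chain '%s' not present in the trajectory", receptor_chain)
  if (!ligand_chain %in% chains)
    stopf("ligand chain '%s' not present in the trajectory", ligand_chain)

  rot <- .stage(outdir, "rotation_series",
                rotation_series(traj, segments))
  utils::write.csv(as.data.frame(rot),
                   file.path(outdir, "rotation_series.csv"), row.names = FALSE)

  cage <- .stage(outdir, "arginine_cage", arginine_cage_state(
    traj, d_res = list(chain = receptor_chain, resid = cage_resids[1]),
    r_res = list(chain = receptor_chain, resid = cage_resids[2]),
    criteria = criteria, stride = stride))
  write_timetable_csv(cage, file.path(outdir, "arginine_cage.csv"))

  tt <- .stage(outdir, "contacts", contact_timetable(
    traj, sprintf("chain %s", receptor_chain),
    sprintf("chain %s", ligand_chain), criteria, stride = stride))
  utils::write.csv(tt$records, file.path(outdir, "contacts.csv"),
                   row.names = FALSE)
  write_timetable_csv(tt, file.path(outdir, "contact_timetable.csv"))
  message(sprintf("[contacts] %d records over %d frames",
                  nrow(tt$records), nrow(tt$counts)))

  comd <- .stage(outdir, "com_distance", com_distance(
    traj, sprintf("chain %s", receptor_chain),
    sprintf("chain %s", ligand_chain)))
  utils::write.csv(comd, file.path(outdir, "com_distance.csv"),
                   row.names = FALSE)

  clus <- NULL
  if (n_frames(traj) >= 2) {
    clus <- .stage(outdir, "clustering", gromos_cluster(
      rmsd_matrix(traj, sprintf("chain %s and name CA", receptor_chain),
                  units = "nm"), cluster_cutoff))
    write_clusters_json(clus, file.path(outdir, "clusters.json"))
    message(sprintf("[clustering] %d clusters at %g nm",
                    length(clus$clusters), cluster_cutoff))
  }

  rama <- .stage(outdir, "ramachandran", {
    pp <- suppressWarnings(phi_psi(get_frame(traj, 1), chain = receptor_chain))
    if (nrow(pp)) ramachandran_summary(pp) else NULL
  })
  if (!is.null(rama)) {
    utils::write.csv(data.frame(class = names(rama$fractions),
                                percent = as.numeric(rama$fractions)),
                     file.path(outdir, "ramachandran.csv"), row.names = FALSE)
  } else {
    utils::write.csv(data.frame(class = character(0), percent = numeric(0)),
                     file.path(outdir, "ramachandran.csv"), row.names = FALSE)
  }

  .write_manifest(outdir, "activation", list(
    receptor_chain = receptor_chain, ligand_chain = ligand_chain,
    cage_resids = cage_resids, cluster_cutoff = cluster_cutoff,
    stride = stride, criteria = unclass(criteria),
    segments = as.data.frame(segments)))
  invisible(list(rotation = rot, cage = cage, contacts = tt,
                 com_distance = comd, clusters = clus, ramachandran = rama))
}

#' Run the pharmacophore-consensus workflow
#'
#' Per receptor conformation: pose clustering at the RMSD cutoff, feature
#' extraction, consensus model with residue annotation. With two or more
#' conformations a pairwise model comparison is written too. Outputs:
#' pose_clusters.json, features.csv, consensus.json, consensus_residues.csv
#' (per conformation), model_comparison.csv, manifest.json.
#'
#' @param poses a `PoseSet` or SDF path
#' @param receptors named list of `Structure`s (or PDB paths); names label the
#'   conformations
#' @param outdir output directory
#' @param pose_cutoff pose-cluster RMSD cutoff, Angstroms (default 2)
#' @param annotation_radius residue annotation radius (default 5)
#' @param min_support minimum ligand support per element (default 10%)
#' @param pki_filter optional c(min, max) pKi filter
#' @return invisibly, list of `ConsensusModel`s
#' @export
run_pharmacophore <- function(poses, receptors, outdir, pose_cutoff = 2.0,
                              annotation_radius = 5.0, min_support = NULL,
                              pki_filter = NULL) {
  if (is.character(poses)) poses <- read_sdf(poses)
  if (!is.null(pki_filter)) {
    poses <- filter_pki(poses, pki_filter[1], pki_filter[2])
    if (length(poses$ligands) == 0) stopf("empty library after pKi filter")
  }
  if (length(poses$ligands) == 0) stopf("empty library: no ligands")
  if (inherits(receptors, "Structure") || is.character(receptors) &&
      length(receptors) == 1 && !is.list(receptors))
    receptors <- list(conf1 = receptors)
  if (is.null(names(receptors)))
    names(receptors) <- paste0("conf", seq_along(receptors))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  pc <- .stage(outdir, "pose_clustering", pose_cluster(poses, pose_cutoff))
  reps <- vapply(pc, function(x) x$representative, integer(1))
  jsonlite::write_json(lapply(pc, function(x) list(
    n_clusters = length(x$result$clusters), sizes = x$result$sizes,
    representative = x$representative)),
    file.path(outdir, "pose_clusters.json"), auto_unbox = TRUE, digits = NA)

  models <- list()
  for (nm in names(receptors)) {
    rec <- receptors[[nm]]
    if (is.character(rec)) rec <- get_frame(read_pdb(rec), 1)
    model <- .stage(outdir, paste0("consensus_", nm), build_consensus(
      poses, rec, representatives = reps, pose_cutoff = pose_cutoff,
      min_support = min_support, annotation_radius = annotation_radius))
    message(sprintf("[consensus_%s] %d features -> %d elements", nm,
                    nrow(model$features), nrow(model$elements)))
    utils::write.csv(model$features,
                     file.path(outdir, sprintf("features_%s.csv", nm)),
                     row.names = FALSE)
    write_consensus(model,
                    csv_path = file.path(outdir,
                      sprintf("consensus_residues_%s.csv", nm)),
                    json_path = file.path(outdir,
                      sprintf("consensus_%s.json", nm)))
    models[[nm]] <- model
  }
  if (length(models) >= 2) {
    cmp <- list()
    nms <- names(models)
    for (i in seq_len(length(nms) - 1)) for (j in (i + 1):length(nms)) {
      r <- compare_models(models[[nms[i]]], models[[nms[j]]])
      if (nrow(r$matched))
        cmp[[length(cmp) + 1]] <- cbind(modelA = nms[i], modelB = nms[j],
                                        r$matched)
    }
    cmp <- if (length(cmp)) do.call(rbind, cmp) else
      data.frame(modelA = character(0), modelB = character(0),
                 type = character(0), shift_A = numeric(0))
    utils::write.csv(cmp, file.path(outdir, "model_comparison.csv"),
                     row.names = FALSE)
  }
  .write_manifest(outdir, "pharmacophore", list(
    pose_cutoff = pose_cutoff, annotation_radius = annotation_radius,
    min_support = min_support, pki_filter = pki_filter,
    conformations = names(receptors)))
  invisible(models)
}

#' Generate a preset fixture bundle
#'
#' Presets: `rotation` (7-TM bundle with a rotation schedule), `approach`
#' (receptor-chemokine complex with planted contacts and an approach
#' schedule), `poses` (ligand pose library with planted feature clusters).
#' Fixtures and their truth tables are written under `outdir`.
#'
#' @param preset one of rotation / approach / poses
#' @param seed RNG seed
#' @param outdir output directory
#' @return invisibly, the generated objects
#' @export
run_simulate <- function(preset = c("rotation", "approach", "poses"),
                         seed = 1, outdir) {
  preset <- match.arg(preset)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  out <- switch(preset,
    rotation = {
      b <- make_tm_bundle(tm_segments_default(extend_tm3 = TRUE,
                                              extend_tm5 = TRUE))
      sched <- matrix(0, 6, 7, dimnames = list(NULL, b$segments$tm))
      sched[2, "TM6"] <- 15; sched[3, "TM1"] <- -45
      sched[4, "TM5"] <- 150; sched[5, "TM6"] <- -15; sched[6, "TM3"] <- 5
      r <- make_rotated_trajectory(b$structure, b$segments, sched,
                                   noise_sd = 0.2, global_motion = TRUE,
                                   seed = seed)
      write_pdb(r$traj, file.path(outdir, "rotation_traj.pdb"))
      utils::write.csv(r$truth, file.path(outdir, "rotation_truth.csv"),
                       row.names = FALSE)
      r
    },
    approach = {
      b <- make_tm_bundle(tm_segments_default(extend_tm3 = TRUE,
                                              extend_tm5 = TRUE))
      lig <- make_ideal_helix(20, chain = "Q", start_resid = 1)
      plants <- list(
        list(a = list(chain = "R", resid = 148, resname = "ASP", atom = "OD1"),
             b = list(chain = "R", resid = 149, resname = "ARG", atom = "NH1"),
             kind = "saltbridge", frames = c(1, 2)),
        list(a = list(chain = "R", resid = 213, resname = "SER", atom = "OG"),
             b = list(chain = "Q", resid = 5, resname = "ASN", atom = "OD1"),
             kind = "hbond", frames = c(2, 3)))
      r <- make_complex_trajectory(b$structure, lig,
                                   approach = c(40, 32, 26),
                                   plants = plants, seed = seed)
      write_pdb(r$traj, file.path(outdir, "complex_traj.pdb"))
      utils::write.csv(r$truth, file.path(outdir, "contact_truth.csv"),
                       row.names = FALSE)
      r
    },
    poses = {
      lib <- make_pose_library(list(
        list(type = "Arm", centroid = c(0, 0, 0), sd = 0.3, n_members = 10),
        list(type = "NIn", centroid = c(12, 0, 0), sd = 0.3, n_members = 10)),
        seed = seed)
      write_sdf(lib$poses, file.path(outdir, "poses.sdf"))
      utils::write.csv(lib$truth$clusters,
                       file.path(outdir, "pose_truth_clusters.csv"),
                       row.names = FALSE)
      utils::write.csv(lib$truth$ligand_features,
                       file.path(outdir, "pose_truth_features.csv"),
                       row.names = FALSE)
      lib
    })
  .write_manifest(outdir, paste0("simulate_", preset), list(seed = seed))
  invisible(out)
}

#' Command-line entry point
#'
#' Subcommands: `activation --traj traj.pdb --receptor-chain R
#' --ligand-chain Q --out outdir`, `pharmacophore --poses poses.sdf
#' --receptor conf.pdb --out outdir`, `simulate --preset
#' {rotation,approach,poses} --seed N --out outdir`.
#'
#' @param args character vector (default `commandArgs(trailingOnly = TRUE)`)
#' @return invisibly, the workflow result
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: gpcrtraj <activation|pharmacophore|simulate> [options]",
    "  activation    --traj FILE --receptor-chain C --ligand-chain C --out DIR",
    "  pharmacophore --poses FILE --receptor FILE[,FILE...] --out DIR",
    "  simulate      --preset rotation|approach|poses --seed N --out DIR",
    sep = "\n")
  if (length(args) < 1) { cat(usage, "\n"); return(invisible(NULL)) }
  cmd <- args[1]
  opt <- function(name, default = NULL) {
    i <- which(args == paste0("--", name))
    if (length(i) == 0) return(default)
    args[i[1] + 1]
  }
  out <- opt("out")
  if (is.null(out)) stopf("--out is required")
  switch(cmd,
    activation = run_activation(
      traj = opt("traj"), receptor_chain = opt("receptor-chain", "R"),
      ligand_chain = opt("ligand-chain", "Q"), outdir = out,
      cluster_cutoff = as.numeric(opt("cluster-cutoff", "0.2")),
      stride = as.integer(opt("stride", "1"))),
    pharmacophore = run_pharmacophore(
      poses = opt("poses"),
      receptors = as.list(strsplit(opt("receptor"), ",")[[1]]),
      outdir = out,
      pose_cutoff = as.numeric(opt("pose-cutoff", "2"))),
    simulate = run_simulate(preset = opt("preset", "rotation"),
                            seed = as.integer(opt("seed", "1")),
                            outdir = out),
    stopf("unknown subcommand '%s'\n%s", cmd, usage))
}
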