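# Receptor "bundle" I/O: a PDB file for coordinates plus a sidecar parameter
# table (PDB carries no charges/LJ) and a JSON metadata file (anchor, box
# centre, planted-pocket bookkeeping), so generated receptors round-trip
# through plain text files.

#' Write a receptor bundle
#'
#' Writes `<stem>.pdb`, `<stem>_params.csv` (per-atom charge and LJ
#' parameters) and `<stem>_meta.json` (anchor, sampling-box centre and, for
#' generated pockets, the planted-landscape metadata).
#'
#' @param model A parameterized [protein_model()].
#' @param stem Output path stem (no extension).
#' @return `stem`, invisibly.
#' @export
write_receptor_bundle <- function(model, stem) {
  write_pdb(model, paste0(stem, ".pdb"))
  write.csv(model$atoms[, c("serial", "charge", "lj_epsilon", "lj_rmin")],
            paste0(stem, "_params.csv"), row.names = FALSE)
  info <- attr(model, "pocket_info")
  pose_to_list <- function(pose) {
    if (is.null(pose)) return(NULL)
    list(translation = pose$translation, rotation = pose$rotation)
  }
  meta <- list(
    anchor = if (!is.null(model$anchor)) {
      list(res_index = model$anchor$res_index,
           atom_name = model$anchor$atom_name)
    },
    pocket_info = if (!is.null(info)) {
      list(
        ligand = info$ligand,
        box_center = info$box_center,
        box_radius = info$box_radius,
        cradle_indices = info$cradle_indices,
        decoy_indices = info$decoy_indices,
        pin_index = info$pin_index,
        decoy_pin_index = info$decoy_pin_index,
        d_star = info$spec$d_star,
        well_depth = info$spec$well_depth,
        seed = info$spec$seed,
        decoy = info$spec$decoy,
        docked_pose = pose_to_list(info$docked_pose),
        min_pose = pose_to_list(info$min_pose)
      )
    }
  )
  jsonlite::write_json(meta, paste0(stem, "_meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(stem)
}

#' Read a receptor bundle
#'
#' @param stem Path stem written by [write_receptor_bundle()].
#' @return A parameterized [protein_model()]; pocket metadata (box centre,
#'   planted-pose bookkeeping) is restored when present.
#' @export
read_receptor_bundle <- function(stem) {
  model <- read_pdb(paste0(stem, ".pdb"))
  par <- utils::read.csv(paste0(stem, "_params.csv"))
  m <- match(model$atoms$serial, par$serial)
  if (anyNA(m)) abort("parameter sidecar does not cover all atoms")
  model$atoms$charge <- par$charge[m]
  model$atoms$lj_epsilon <- par$lj_epsilon[m]
  model$atoms$lj_rmin <- par$lj_rmin[m]
  meta_path <- paste0(stem, "_meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(meta$anchor)) {
      model <- set_anchor(model, meta$anchor$res_index, meta$anchor$atom_name)
    }
    if (!is.null(meta$pocket_info)) {
      pi_ <- meta$pocket_info
      template <- load_ligand_template(pi_$ligand)
      list_to_pose <- function(lst) {
        if (is.null(lst)) return(NULL)
        ligand_pose(template, translation = as.numeric(lst$translation),
                    rotation = quat_normalize(as.numeric(lst$rotation)))
      }
      spec <- pocket_spec(
        d_star = pi_$d_star, well_depth = pi_$well_depth,
        decoy = if (!is.null(pi_$decoy) && length(pi_$decoy)) {
          list(d2 = pi_$decoy$d2, depth2 = pi_$decoy$depth2)
        },
        seed = pi_$seed
      )
      attr(model, "pocket_info") <- list(
        spec = spec, ligand = pi_$ligand,
        docked_pose = list_to_pose(pi_$docked_pose),
        min_pose = list_to_pose(pi_$min_pose),
        cradle_indices = as.integer(pi_$cradle_indices),
        decoy_indices = as.integer(pi_$decoy_indices),
        pin_index = as.integer(pi_$pin_index),
        decoy_pin_index = as.integer(pi_$decoy_pin_index),
        box_center = as.numeric(pi_$box_center),
        box_radius = if (!is.null(pi_$box_radius)) as.numeric(pi_$box_radius)
      )
    }
  }
  model
}
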