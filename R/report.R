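#' Amino-acid composition of a sequence
#'
#' Percentages are taken over the counted standard residues; `X`
#' (unknown) is excluded from the denominator. Charged = D, E, K, R, H;
#' aromatic = F, W, Y.
#'
#' @param sequence Non-empty one-letter character string.
#' @return A list of class `aa_composition`: `freq` (tibble `aa`, `count`,
#'   `pct` over the 20 standard residues), `length` (counted residues),
#'   `pro_pct`, `ala_pct`, `aromatic_pct`, `charged_pct`.
#' @examples
#' aa_composition("PPPA")$pro_pct  # 75
#' @export
aa_composition <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 || !nzchar(sequence))
    abort("sequence must be a non-empty string")
  chars <- strsplit(toupper(sequence), "")[[1]]
  chars <- chars[chars != "X"]
  if (length(chars) == 0) abort("sequence contains no standard residues")
  bad <- setdiff(chars, AA_STANDARD)
  if (length(bad) > 0)
    abort(paste0("non-standard letters in sequence: ",
                 paste(unique(bad), collapse = "")))
  counts <- table(factor(chars, levels = AA_STANDARD))
  n <- length(chars)
  freq <- tibble(aa = AA_STANDARD, count = as.integer(counts),
                 pct = 100 * as.integer(counts) / n)
  pct_of <- function(set) sum(freq$pct[freq$aa %in% set])
  structure(list(freq = freq, length = n,
                 pro_pct = pct_of("P"), ala_pct = pct_of("A"),
                 aromatic_pct = pct_of(c("F", "W", "Y")),
                 charged_pct = pct_of(c("D", "E", "K", "R", "H"))),
            class = "aa_composition")
}

#' @export
print.aa_composition <- function(x, ...) {
  cat(sprintf(
    "<aa_composition> %d residues | Pro %.1f%%  Ala %.1f%%  aromatic %.1f%%  charged %.1f%%\n",
    x$length, x$pro_pct, x$ala_pct, x$aromatic_pct, x$charged_pct))
  invisible(x)
}

#' Volume contraction upon oligomer formation
#'
#' `delta2 = b - 2a` (dimer contraction) and `delta4 = c - 4a` (tetramer
#' contraction), where `a`, `b`, `c` are the monomer, dimer and tetramer
#' grid volumes. Negative values indicate densification on assembly; the
#' sign is the robust, headline property (the magnitudes sit at the
#' reproducibility limit of grid methods).
#'
#' @param a,b,c Monomer, dimer and tetramer volumes (Angstrom^3, > 0).
#' @return One-row tibble with `delta2` and `delta4`.
#' @export
volume_contraction <- function(a, b, c) {
  if (any(c(a, b, c) <= 0)) abort("volumes must be positive")
  tibble(delta2 = b - 2 * a, delta4 = c - 4 * a)
}

#' Configuration for a comparative report
#'
#' @param temperatures Named numeric vector: entry id -> optimal growth
#'   temperature (degrees C), used only to order the report rows.
#' @param probe_radius Probe radius for surface areas and cavities
#'   (Angstrom).
#' @param grid_spacing Grid spacing for volumes and cavities (Angstrom).
#' @param n_sphere_points Sphere sample count for surface areas.
#' @param cutoffs Per-kind contact cutoffs (see [find_contacts()]).
#' @param pvalue_samples Null patches per hydrophobic P-value (0 disables
#'   P-value computation).
#' @param seed Seed for the P-value sampler.
#' @return A list of class `report_config`.
#' @export
report_config <- function(temperatures = NULL, probe_radius = 1.4,
                          grid_spacing = 1.0, n_sphere_points = 960,
                          cutoffs = list(), pvalue_samples = 2000,
                          seed = 1) {
  structure(list(temperatures = temperatures, probe_radius = probe_radius,
                 grid_spacing = grid_spacing,
                 n_sphere_points = n_sphere_points, cutoffs = cutoffs,
                 pvalue_samples = pvalue_samples, seed = seed),
            class = "report_config")
}

#' Build a comparative compactness and interface report
#'
#' For each entry: resolves a tetrameric assembly (four deposited polymer
#' chains, else the deposited assembly transforms), then computes the
#' monomer volume `a` (mean over chains), the tight-dimer volume `b`, the
#' assembly volume `c`, the contraction deltas `delta2 = b - 2a` /
#' `delta4 = c - 4a`, the assembly surface area and surface-to-volume
#' ratio (assembly SASA over assembly grid volume), cavities of the first
#' chain, intra-monomer salt-bridge/H-bond counts of the first chain, and
#' the per-pair interface classification. Entries that cannot be resolved
#' to an assembly are recorded as errors and the run continues.
#'
#' @param models List of [struct_model()] objects.
#' @param config A [report_config()].
#' @return A list of class `comparative_report`: `rows` (one per entry,
#'   Table-2-like), `interface_rows` (one per chain pair, Table-3-like),
#'   `intra_monomer` (per-entry intra-chain counts), `errors`, `config`.
#' @export
build_comparative_report <- function(models, config = report_config()) {
  stopifnot(inherits(config, "report_config"))
  radii <- vdw_radii()
  rows <- list(); iface <- list(); intra <- list(); errors <- list()
  for (model in models) {
    id <- model$entry_id
    res <- tryCatch(
      report_one_entry(model, config, radii),
      error = function(e) e)
    if (inherits(res, "error")) {
      errors[[id]] <- conditionMessage(res)
      next
    }
    rows[[id]] <- res$row
    iface[[id]] <- res$iface
    intra[[id]] <- res$intra
  }
  rows <- bind_rows(rows)
  if (nrow(rows) > 0 && !is.null(config$temperatures)) {
    rows$growth_temp <- unname(config$temperatures[rows$entry_id])
    rows <- arrange(rows, .data$growth_temp)
  }
  structure(list(rows = rows, interface_rows = bind_rows(iface),
                 intra_monomer = bind_rows(intra), errors = errors,
                 config = config),
            class = "comparative_report")
}

report_one_entry <- function(model, config, radii) {
  asm <- resolve_tetramer(model)
  ids <- chain_ids(asm)
  sp <- config$grid_spacing

  vol_chain <- vapply(ids, function(ch)
    grid_volume(model_chain(asm, ch), radii, sp, probe = 0)$volume,
    numeric(1))
  a <- mean(vol_chain)
  cmap <- classify_assembly_interfaces(
    asm, radii, probe = config$probe_radius,
    n_points = config$n_sphere_points, cutoffs = config$cutoffs)
  tight <- filter(cmap$labels, .data$label == "tight_dimer")
  if (nrow(tight) == 0)
    abort("no tight dimer found in assembly")
  dimer_atoms <- bind_rows(model_chain(asm, tight$chain1[1]),
                           model_chain(asm, tight$chain2[1]))
  b <- grid_volume(dimer_atoms, radii, sp, probe = 0)$volume
  c_vol <- grid_volume(polymer_atoms(asm), radii, sp, probe = 0)$volume
  deltas <- volume_contraction(a, b, c_vol)

  sasa_tet <- shrake_rupley_sasa(polymer_atoms(asm), radii,
                                 probe = config$probe_radius,
                                 n_points = config$n_sphere_points)
  cav <- detect_cavities(model_chain(asm, ids[1]), radii, sp,
                         probe = config$probe_radius)

  mono <- struct_model(model_chain(asm, ids[1]), entry_id = asm$entry_id)
  sb <- find_salt_bridges(mono, cutoff = config$cutoffs$salt_bridge %||% 3.5)
  hb <- find_hbonds(mono, cutoff = config$cutoffs$hbond %||% 3.5)

  row <- tibble(
    entry_id = asm$entry_id,
    monomer_volume = a, dimer_volume = b, tetramer_volume = c_vol,
    delta2 = deltas$delta2, delta4 = deltas$delta4,
    surface_area = sasa_tet$total_area,
    sv_ratio = sasa_tet$total_area / c_vol,
    cavity_total = sum(cav$volume), cavity_count = nrow(cav))

  iface <- tidy(cmap) |> mutate(entry_id = asm$entry_id, .before = 1)
  if (config$pvalue_samples > 0) {
    iface$hydrophobic_p <- vapply(seq_len(nrow(iface)), function(k) {
      if (iface$interface_area[k] <= 0) return(NA_real_)
      as.numeric(hydrophobic_pvalue(
        asm, c(iface$chain1[k], iface$chain2[k]),
        n_samples = config$pvalue_samples, seed = config$seed,
        radii = radii, probe = config$probe_radius,
        n_points = config$n_sphere_points))
    }, numeric(1))
  }
  iface$tetramer_buried_area <- cmap$tetramer_buried_area

  intra <- tibble(
    entry_id = asm$entry_id, chain = ids[1],
    n_salt_bridges = nrow(sb),
    n_hbonds = sum(hb$n_atom_pairs))

  list(row = row, iface = iface, intra = intra)
}

# four polymer chains already deposited, else expand the deposited
# assembly transforms
resolve_tetramer <- function(model) {
  if (length(chain_ids(model)) == 4) return(model)
  if (!is.null(model$transforms)) {
    asm <- build_assembly(model)
    if (length(chain_ids(asm)) == 4) return(asm)
    abort(paste0("deposited assembly of ", model$entry_id, " has ",
                 length(chain_ids(asm)), " chains, not 4"))
  }
  abort(paste0(model$entry_id,
               ": no tetrameric assembly obtainable (chains: ",
               length(chain_ids(model)), ", no transforms)"))
}

#' @export
print.comparative_report <- function(x, ...) {
  cat("<comparative_report> ", nrow(x$rows), " entries\n", sep = "")
  if (nrow(x$rows) > 0) print(as.data.frame(x$rows), digits = 4)
  if (length(x$errors) > 0) {
    cat("errors:\n")
    for (id in names(x$errors)) cat("  ", id, ": ", x$errors[[id]], "\n")
  }
  invisible(x)
}

#' @rdname quatstab-tidiers
#' @export
tidy.comparative_report <- function(x, ...) x$rows

#' @rdname quatstab-tidiers
#' @export
glance.comparative_report <- function(x, ...) {
  tibble(n_entries = nrow(x$rows), n_errors = length(x$errors),
         n_delta4_negative = sum(x$rows$delta4 < 0),
         n_delta4_positive = sum(x$rows$delta4 > 0))
}

#' Serialise / read back a comparative report (JSON)
#'
#' The JSON round-trip preserves every numeric field at full precision
#' (no rounding), so identical inputs and configuration give
#' byte-identical files.
#'
#' @param report A `comparative_report`.
#' @param path File path.
#' @return `write_report_json()` returns `path` invisibly;
#'   `read_report_json()` returns a `comparative_report`.
#' @export
write_report_json <- function(report, path) {
  payload <- list(
    rows = report$rows, interface_rows = report$interface_rows,
    intra_monomer = report$intra_monomer,
    errors = report$errors,
    config = unclass(report$config))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- payload$config
  temps <- unlist(cfg$temperatures)
  structure(
    list(rows = as_tibble(payload$rows),
         interface_rows = as_tibble(payload$interface_rows),
         intra_monomer = as_tibble(payload$intra_monomer),
         errors = as.list(payload$errors),
         config = report_config(
           temperatures = temps, probe_radius = cfg$probe_radius,
           grid_spacing = cfg$grid_spacing,
           n_sphere_points = cfg$n_sphere_points,
           cutoffs = as.list(cfg$cutoffs),
           pvalue_samples = cfg$pvalue_samples, seed = cfg$seed)),
    class = "comparative_report")
}
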