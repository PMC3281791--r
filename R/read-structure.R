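#' Read a macromolecular structure file
#'
#' Parses a PDB or mmCIF file into a [struct_model()]. Only the first model
#' of multi-model files is kept; alternate locations are resolved by
#' keeping the highest-occupancy conformer (alphabetical alt-loc id breaks
#' ties); hydrogens are dropped (all downstream cutoffs are heavy-atom
#' based); waters and non-polymer hetero groups (e.g. SAM/SAH cofactors)
#' are flagged `het` and excluded from every area, volume and contact
#' computation. Deposited biological-assembly instructions (PDB REMARK 350,
#' mmCIF `pdbx_struct_assembly_gen` / `pdbx_struct_oper_list`) are captured;
#' when several assemblies exist the first one generating four polymer
#' chain copies is preselected, otherwise [build_assembly()] requires an
#' explicit transform list.
#'
#' @param path Path to the structure file.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by file extension).
#' @return A [struct_model()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("[.]gz$", "", path)))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  pdb <- withCallingHandlers(
    tryCatch(
      if (format == "pdb")
        bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
      else bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE),
      error = function(e)
        abort(paste0("cannot parse ", format, " file '", path, "': ",
                     conditionMessage(e)))
    ),
    warning = function(w) {
      # silence the reader's advisory notes; real problems still surface
      if (grepl("beta version|helix/sheet", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  at <- as_tibble(pdb$atom)
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$b[is.na(at$b)] <- 0
  at$chain[is.na(at$chain)] <- "A"

  element <- infer_elements(at$elesy, at$elety, at$type)
  at$element <- element

  at <- at |>
    filter(!.data$element %in% c("H", "D")) |>
    resolve_altloc()

  het <- (at$type == "HETATM" & !toupper(at$resid) %in% names(AA_3TO1)) |
    toupper(at$resid) %in% c("HOH", "DOD", "WAT")

  atoms <- tibble(
    chain = at$chain, resno = at$resno, insert = at$insert,
    resname = toupper(at$resid), elety = at$elety, alt = at$alt,
    element = at$element, x = at$x, y = at$y, z = at$z,
    occupancy = pmin(pmax(at$o, 0), 1), b = at$b, het = het
  )

  seqres <- NULL
  if (!is.null(pdb$seqres) && length(pdb$seqres) > 0) {
    sr_chain <- names(pdb$seqres)
    if (is.null(sr_chain)) sr_chain <- rep("A", length(pdb$seqres))
    seqres <- split(unname(toupper(pdb$seqres)), sr_chain)
  }

  lines <- readLines(path, warn = FALSE)
  if (format == "pdb") {
    assemblies <- parse_remark350(lines)
    sg <- parse_cryst1_sg(lines)
  } else {
    assemblies <- parse_cif_assemblies(lines)
    sg <- parse_cif_sg(lines)
  }

  entry_id <- toupper(tools::file_path_sans_ext(basename(path)))
  m <- struct_model(atoms, entry_id = entry_id, seqres = seqres,
                    transforms = NULL, space_group = sg)
  m$assemblies <- assemblies
  m$transforms <- choose_assembly(assemblies, chain_ids(m))
  m
}

# Keep, per (chain, residue, atom name), the alternate location with the
# highest occupancy; ties broken by alphabetical alt-loc id.
resolve_altloc <- function(at) {
  at |>
    mutate(.row = row_number()) |>
    group_by(.data$chain, .data$resno, .data$insert, .data$resid,
             .data$elety) |>
    arrange(dplyr::desc(.data$o), .data$alt, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    arrange(.data$.row) |>
    select(-".row")
}

TWO_LETTER_ELEMENTS <- c("FE", "ZN", "MG", "MN", "CL", "BR", "NA", "SE",
                         "NI", "CU", "CO", "CD", "HG", "MO", "PT", "AU")

infer_elements <- function(elesy, elety, type) {
  element <- toupper(trimws(as.character(elesy)))
  known <- c("H", "D", "C", "N", "O", "S", "P", "F", "I", "K", "B", "U",
             "W", "CA", TWO_LETTER_ELEMENTS)
  bad <- is.na(element) | !nzchar(element) | !(element %in% known)
  if (any(bad)) {
    warn("element symbol missing or unrecognised for some atoms; inferring from atom names")
    guess <- toupper(gsub("[^A-Za-z]", "", elety[bad]))
    # metals and halides appear as HETATM with the full symbol as the name
    two <- substr(guess, 1, 2)
    el <- substr(guess, 1, 1)
    use2 <- type[bad] == "HETATM" & two %in% TWO_LETTER_ELEMENTS
    el[use2] <- two[use2]
    el[substr(guess, 1, 1) %in% c("H", "D") &
         grepl("^[0-9]", elety[bad])] <- "H"
    element[bad] <- el
  }
  element
}

parse_cryst1_sg <- function(lines) {
  cl <- lines[startsWith(lines, "CRYST1")]
  if (length(cl) == 0) return(NA_character_)
  trimws(substr(cl[1], 56, 66))
}

parse_cif_sg <- function(lines) {
  hit <- grep("^_symmetry\\.space_group_name_H-M", lines, value = TRUE)
  if (length(hit) == 0) return(NA_character_)
  val <- sub("^_symmetry\\.space_group_name_H-M\\s+", "", hit[1])
  gsub("^['\"]|['\"]$", "", trimws(val))
}

#' Create an assembly transform
#'
#' @param rotation 3x3 orthonormal rotation matrix (proper; checked to
#'   1e-6 on orthonormality and determinant).
#' @param translation Length-3 translation vector (Angstrom).
#' @param chains Chain ids the transform applies to, or `NULL` for all
#'   polymer chains.
#' @param op_id Operator identifier.
#' @return A list of class `assembly_transform`.
#' @export
assembly_transform <- function(rotation, translation = c(0, 0, 0),
                               chains = NULL, op_id = "1") {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3)
  if (max(abs(rotation %*% t(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6)
    abort("rotation must be orthonormal with determinant 1 (no reflection)")
  structure(list(rotation = rotation, translation = translation,
                 chains = chains, op_id = as.character(op_id)),
            class = "assembly_transform")
}

# REMARK 350 -> list of assemblies; each assembly is a list of
# assembly_transform objects.
parse_remark350 <- function(lines) {
  rl <- lines[startsWith(lines, "REMARK 350")]
  if (length(rl) == 0) return(list())
  assemblies <- list()
  cur <- NULL
  chains <- NULL
  mat <- matrix(NA_real_, 3, 4)
  op <- NA_character_
  flush_op <- function() {
    if (!is.na(op) && all(is.finite(mat))) {
      cur[[length(cur) + 1]] <<- assembly_transform(
        rotation = mat[, 1:3], translation = mat[, 4],
        chains = chains, op_id = op)
    }
    mat <<- matrix(NA_real_, 3, 4)
    op <<- NA_character_
  }
  for (ln in rl) {
    body <- substr(ln, 11, nchar(ln))
    if (grepl("BIOMOLECULE:", body)) {
      flush_op()
      if (!is.null(cur)) assemblies[[length(assemblies) + 1]] <- cur
      cur <- list()
      chains <- NULL
    } else if (grepl("APPLY THE FOLLOWING TO CHAINS:", body)) {
      flush_op()
      ch <- sub(".*CHAINS:", "", body)
      chains <- trimws(strsplit(ch, ",")[[1]])
      chains <- chains[nzchar(chains)]
    } else if (grepl("AND CHAINS:", body)) {
      ch <- sub(".*CHAINS:", "", body)
      extra <- trimws(strsplit(ch, ",")[[1]])
      chains <- c(chains, extra[nzchar(extra)])
    } else if (grepl("^\\s*BIOMT[123]", body)) {
      tok <- strsplit(trimws(body), "\\s+")[[1]]
      row <- as.integer(sub("BIOMT", "", tok[1]))
      this_op <- tok[2]
      if (!is.na(op) && this_op != op) flush_op()
      op <- this_op
      mat[row, ] <- as.numeric(tok[3:6])
      if (row == 3) flush_op()
    }
  }
  flush_op()
  if (!is.null(cur)) assemblies[[length(assemblies) + 1]] <- cur
  assemblies[lengths(assemblies) > 0]
}

# Minimal mmCIF assembly parsing: pdbx_struct_assembly_gen (which operators
# apply to which asym ids) plus pdbx_struct_oper_list (the matrices).
parse_cif_assemblies <- function(lines) {
  gen <- read_cif_category(lines, "_pdbx_struct_assembly_gen")
  ops <- read_cif_category(lines, "_pdbx_struct_oper_list")
  if (is.null(gen) || is.null(ops)) return(list())
  opmap <- list()
  for (i in seq_len(nrow(ops))) {
    R <- matrix(NA_real_, 3, 3)
    tr <- rep(NA_real_, 3)
    for (r in 1:3) {
      for (cc in 1:3)
        R[r, cc] <- as.numeric(ops[[paste0("matrix[", r, "][", cc, "]")]][i])
      tr[r] <- as.numeric(ops[[paste0("vector[", r, "]")]][i])
    }
    opmap[[ops$id[i]]] <- list(rotation = R, translation = tr)
  }
  assemblies <- list()
  for (i in seq_len(nrow(gen))) {
    aid <- gen$assembly_id[i]
    opids <- expand_oper_expression(gen$oper_expression[i])
    chains <- trimws(strsplit(gen$asym_id_list[i], ",")[[1]])
    tfs <- lapply(opids, function(oid) {
      o <- opmap[[oid]]
      if (is.null(o)) return(NULL)
      assembly_transform(o$rotation, o$translation, chains = chains,
                         op_id = oid)
    })
    tfs <- tfs[!vapply(tfs, is.null, logical(1))]
    if (length(tfs) > 0) {
      if (length(assemblies) < as.numeric(aid) || is.na(as.numeric(aid)))
        assemblies[[length(assemblies) + 1]] <- tfs
      else
        assemblies[[as.numeric(aid)]] <- c(assemblies[[as.numeric(aid)]], tfs)
    }
  }
  assemblies
}

# "1,2,3", "(1-4)", "1" -> character vector of operator ids. Cartesian
# compositions ("(X0)(1-60)") are out of scope and rejected.
expand_oper_expression <- function(expr) {
  expr <- gsub("\\s", "", expr)
  if (grepl("\\)\\(", expr))
    abort(paste0("composed operator expressions not supported: ", expr))
  expr <- gsub("[()']", "", expr)
  parts <- strsplit(expr, ",")[[1]]
  out <- character()
  for (p in parts) {
    if (grepl("^\\d+-\\d+$", p)) {
      rng <- as.integer(strsplit(p, "-")[[1]])
      out <- c(out, as.character(seq(rng[1], rng[2])))
    } else out <- c(out, p)
  }
  out
}

# Very small mmCIF category reader (loop_ or key-value form).
read_cif_category <- function(lines, cat) {
  pref <- paste0(cat, ".")
  idx <- which(startsWith(trimws(lines), pref))
  if (length(idx) == 0) return(NULL)
  first <- idx[1]
  in_loop <- any(trimws(lines[max(1, first - 1)]) == "loop_")
  if (in_loop) {
    fields <- character()
    i <- first
    while (i <= length(lines) && startsWith(trimws(lines[i]), pref)) {
      fields <- c(fields, sub(pref, "", trimws(lines[i]), fixed = TRUE))
      i <- i + 1
    }
    rows <- list()
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (!nzchar(ln) || startsWith(ln, "_") || ln %in% c("loop_", "#") ||
          startsWith(ln, "#")) break
      rows[[length(rows) + 1]] <- scan(text = ln, what = character(),
                                       quiet = TRUE)
      i <- i + 1
    }
    if (length(rows) == 0) return(NULL)
    m <- do.call(rbind, rows)
    if (ncol(m) != length(fields)) return(NULL)
    df <- as_tibble(as.data.frame(m, stringsAsFactors = FALSE))
    names(df) <- fields
    df
  } else {
    # key-value form: one row
    vals <- list()
    for (i in idx) {
      ln <- trimws(lines[i])
      key <- sub("\\s.*$", "", ln)
      val <- trimws(sub("^\\S+\\s*", "", ln))
      if (!nzchar(val) && i + 1 <= length(lines))
        val <- trimws(lines[i + 1])
      vals[[sub(pref, "", key, fixed = TRUE)]] <-
        gsub("^['\"]|['\"]$", "", val)
    }
    as_tibble(vals)
  }
}

# First assembly expanding to exactly four polymer chain copies, else the
# single deposited assembly, else NULL (explicit user choice required).
choose_assembly <- function(assemblies, polymer_chains) {
  if (length(assemblies) == 0) return(NULL)
  n_copies <- vapply(assemblies, function(tfs) {
    sum(vapply(tfs, function(tf) {
      ch <- if (is.null(tf$chains)) polymer_chains
            else intersect(tf$chains, polymer_chains)
      length(ch)
    }, numeric(1)))
  }, numeric(1))
  tet <- which(n_copies == 4)
  if (length(tet) > 0) return(assemblies[[tet[1]]])
  if (length(assemblies) == 1) return(assemblies[[1]])
  NULL
}
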