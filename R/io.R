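#' Read a motion/storage text file
#'
#' Parses the OpenSim-style storage text dialect (`.sto`/`.mot`: free-form
#' header lines through `endheader`, then a tab/space-delimited table whose
#' first column is time) and plain CSV. Angle columns of files declaring
#' `inDegrees=yes` are converted to radians when `to_radians = TRUE`.
#'
#' @param path File path.
#' @param dialect `"sto"`, `"mot"` or `"csv"`; default guessed from the
#'   extension.
#' @param to_radians Convert all non-time columns from degrees to radians
#'   if the header declares degrees (default `TRUE`).
#' @return A tibble (first column `time`, strictly increasing) with
#'   attributes `header` (named list) and `in_degrees`.
#' @export
read_motion_file <- function(path, dialect = NULL, to_radians = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dialect <- dialect %||% tolower(tools::file_ext(path))
  if (!dialect %in% c("sto", "mot", "csv")) {
    stop("unknown dialect: ", dialect, call. = FALSE)
  }
  if (dialect == "csv") {
    df <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
    header <- list()
    in_degrees <- FALSE
  } else {
    lines <- readLines(path, warn = FALSE)
    end <- match(TRUE, trimws(lines) == "endheader")
    if (is.na(end)) stop("malformed header: no 'endheader' line", call. = FALSE)
    hdr_lines <- lines[seq_len(end - 1)]
    header <- list()
    for (hl in hdr_lines) {
      if (grepl("=", hl, fixed = TRUE)) {
        kv <- strsplit(hl, "=", fixed = TRUE)[[1]]
        header[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
      }
    }
    in_degrees <- tolower(header[["inDegrees"]] %||% "no") == "yes"
    body <- lines[(end + 1):length(lines)]
    body <- body[nzchar(trimws(body))]
    cols <- strsplit(trimws(body[1]), "[ \t]+")[[1]]
    rows <- lapply(seq_along(body[-1]), function(i) {
      vals <- strsplit(trimws(body[i + 1]), "[ \t]+")[[1]]
      if (length(vals) != length(cols)) {
        stop(sprintf("line %d: %d values for %d columns", end + 1 + i,
                     length(vals), length(cols)), call. = FALSE)
      }
      as.numeric(vals)
    })
    df <- tibble::as_tibble(do.call(rbind, rows), .name_repair = "minimal")
    names(df) <- cols
    declared_rows <- suppressWarnings(as.integer(header[["nRows"]]))
    if (isTRUE(!is.na(declared_rows)) && declared_rows != nrow(df)) {
      stop(sprintf("header declares %d rows but %d present", declared_rows,
                   nrow(df)), call. = FALSE)
    }
    declared_cols <- suppressWarnings(as.integer(header[["nColumns"]]))
    if (isTRUE(!is.na(declared_cols)) && declared_cols != ncol(df)) {
      stop(sprintf("header declares %d columns but %d present", declared_cols,
                   ncol(df)), call. = FALSE)
    }
  }
  if (names(df)[1] != "time") names(df)[1] <- "time"
  if (any(!is.finite(as.matrix(df)))) stop("missing or non-numeric cells", call. = FALSE)
  if (is.unsorted(df$time, strictly = TRUE)) {
    stop("time column must be strictly increasing", call. = FALSE)
  }
  if (in_degrees && to_radians) {
    df[-1] <- df[-1] * pi / 180
    in_degrees <- FALSE
  }
  attr(df, "header") <- header
  attr(df, "in_degrees") <- in_degrees
  df
}

#' Write a motion/storage text file
#'
#' @param df Data frame whose first column is `time`.
#' @param path Output path (`.sto`/`.mot` dialect).
#' @param name Table name recorded in the header.
#' @param notes Optional extra header comment lines.
#' @return `path`, invisibly.
#' @export
write_motion_file <- function(df, path, name = "gaitmet", notes = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("name=", name),
    paste0("version=1"),
    notes,
    paste0("nRows=", nrow(df)),
    paste0("nColumns=", ncol(df)),
    "inDegrees=no",
    "endheader"
  ), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  lines <- apply(as.matrix(df), 1, function(r) {
    paste(formatC(r, format = "g", digits = 15), collapse = "\t")
  })
  writeLines(lines, con)
  invisible(path)
}

# linear interpolation of a long moment-arm table onto new times
arms_at_times <- function(arms, times) {
  arms |>
    dplyr::group_by(.data$muscle, .data$joint) |>
    dplyr::reframe(arm = stats::approx(.data$time, .data$arm, xout = times,
                                       rule = 2)$y,
                   time = times)
}

default_muscle_groups <- function() {
  tibble::tribble(
    ~muscle, ~joint, ~group,
    "iliopsoas", "hip", "hip flexors",
    "glutmax", "hip", "hip extensors",
    "hamstrings", "hip", "hip extensors",
    "hamstrings", "knee", "knee flexors",
    "recfem", "hip", "hip flexors",
    "recfem", "knee", "knee extensors",
    "vasti", "knee", "knee extensors",
    "bfsh", "knee", "knee flexors",
    "gastroc", "knee", "knee flexors",
    "gastroc", "ankle", "ankle plantarflexors",
    "soleus", "ankle", "ankle plantarflexors",
    "tibant", "ankle", "ankle dorsiflexors"
  )
}

#' Run the full analysis pipeline on a synthetic subject
#'
#' Orchestrates the stages in order: generate (or accept) a virtual subject
#' and trials, optionally calibrate passive parameters, solve the
#' redundancy problem per trial under the requested workflow, evaluate the
#' requested metabolic energy models, and aggregate whole-body,
#' muscle-group and gait-phase energetics.
#'
#' @param config Named list: `seed`, `speeds`, `workflow`, `models`,
#'   `basal` (W/kg), `calibrate` (logical), `n_mesh`, `out_dir` (optional;
#'   reports and solutions written there), `subject`/`trials` (optional
#'   pre-built objects).
#' @return List with `report` (tibble: one row per trial x model with the
#'   whole-body rate and phase shares), `group_shares`, `solutions`,
#'   `subject`, `trials`, `config`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- utils::modifyList(list(
    seed = 1, speeds = 1.3, workflow = "PAS", models = c("BH04", "UM10"),
    basal = 1.2, calibrate = FALSE, n_mesh = 50, out_dir = NULL
  ), config)
  bad <- setdiff(cfg$models, metabolic_model_ids())
  if (length(bad) > 0) stop("unknown metabolic models: ",
                            paste(bad, collapse = ", "), call. = FALSE)
  subject <- cfg$subject %||% make_virtual_subject(cfg$seed)
  trials <- cfg$trials %||% lapply(seq_along(cfg$speeds), function(i) {
    make_gait_trial(subject, cfg$speeds[i], seed = i)
  })
  muscles <- subject$muscles
  if (isTRUE(cfg$calibrate)) {
    grids <- list(hip = seq(-0.4, 1.0, length.out = 15),
                  knee = seq(0.0, 1.6, length.out = 15),
                  ankle = seq(-0.5, 0.5, length.out = 15))
    targets <- dplyr::bind_rows(lapply(subject$dofs, function(j) {
      simulate_passive_joint_moment(subject, muscles, j, grids[[j]])
    }))
    cal <- calibrate_passive_params(targets, subject, muscles, seed = cfg$seed)
    muscles <- cal$muscles
  }
  groups <- default_muscle_groups()
  rows <- list(); shares_all <- list(); solutions <- list()
  for (i in seq_along(trials)) {
    trial <- trials[[i]]
    sol <- solve_redundancy(trial, muscles, cfg$workflow,
                            opts = list(n_mesh = cfg$n_mesh))
    solutions[[i]] <- sol
    for (model in cfg$models) {
      met <- compute_metabolic_rates(model, sol, muscles)
      wb <- whole_body_average(met, trial$body_mass, basal = cfg$basal)
      total <- met |>
        dplyr::group_by(.data$time) |>
        dplyr::summarise(e_dot = sum(.data$e_dot), .groups = "drop")
      ph <- phase_relative_cost(total$time, total$e_dot, trial$events$toe_off)
      arms_i <- arms_at_times(trial$arms, unique(met$time))
      att <- split_biarticular(met, arms_i)
      gr <- muscle_group_rates(att, groups)
      rows[[length(rows) + 1]] <- tibble::tibble(
        speed = trial$speed, workflow = cfg$workflow, model = model,
        whole_body_w_kg = wb, stance_pct = ph$stance, swing_pct = ph$swing,
        cycle_energy_j_kg = (wb - cfg$basal) * trial$cycle_duration,
        trial = i
      )
      shares_all[[length(shares_all) + 1]] <- gr$shares |>
        dplyr::mutate(speed = trial$speed, model = model, trial = i)
    }
  }
  report <- dplyr::bind_rows(rows)
  group_shares <- dplyr::bind_rows(shares_all)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report, file.path(cfg$out_dir, "energy_report.csv"),
                     row.names = FALSE)
    utils::write.csv(group_shares, file.path(cfg$out_dir, "group_shares.csv"),
                     row.names = FALSE)
  }
  list(report = report, group_shares = group_shares, solutions = solutions,
       subject = subject, trials = trials, config = cfg)
}
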