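# Shared fixtures, built in code.

# Degenerate one-compartment model: all flows zero, plasma volume 1 L,
# fraction unbound 1, a single first-order renal clearance from plasma.
# Closed form: C(t) = C0 * exp(-(cl/V) * t).
one_compartment_model <- function(cl = 0.01, v_plasma = 1) {
  phys <- physiology(
    body_weight = 0.025,
    compartment_volumes = c(plasma = v_plasma, liver_blood = 1e-3,
                            hepatocyte = 1e-3, kidney = 1e-3, rest_of_body = 1e-3),
    blood_flows = c(liver = 0, kidney = 0, rest_of_body = 0),
    gfr = cl, bile_flow = 0
  )
  model_definition(
    phys,
    species = list(chem_species("drug", 300, 1)),
    processes = list(p_glomerular_filtration("drug", cl)),
    name = "one_compartment"
  )
}

mdz_model <- function() get_family_model("midazolam")
mdz_dose <- function() list(family_dose("midazolam", 0.025))

# Cirrhosis scenario with the published transporter fold changes
# (Abcc3 log2FC 1.69, Abcc4 log2FC 3.95) and CYP activity at 11%.
default_scenario <- function() {
  cirrhosis_scenario(0.11, scaling_map(
    c(Abcc3 = 2^1.69, Abcc4 = 2^3.95),
    c(Abcc3 = "from_log2fc(1.69)", Abcc4 = "from_log2fc(3.95)")
  ))
}

noise_free <- function() {
  noise_model(cv = 0, iiv_cv = 0,
              loq = c(plasma_conc = 0, urine_cumulative = 0, bile_cumulative = 0))
}

plasma_only <- function(obs) obs[obs$kind == "plasma_conc", , drop = FALSE]

# Published mouse DE summary rows (gene, log2FC, FDR) used as input data.
published_mouse_de <- function() {
  de_table(data.frame(
    gene_symbol = c("Abcc3", "Abcc4", "Cyp1a2", "Cyp2c29", "Cyp2d22", "Cyp3a11"),
    log2fc = c(1.69, 3.95, -1.69, -1.92, -0.18, 0.30),
    fdr = c(3.28e-9, 9.07e-19, 4.07e-7, 1.01e-9, 0.23, 0.46),
    stringsAsFactors = FALSE
  ), species = "mouse")
}
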