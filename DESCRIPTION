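Package: isoclock
Title: Hydrogen Isotope Exchange Clocks for Dissolved Acetate
Version: 0.1.0
Authors@R: person("isoclock", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Tools for inferring residence times and turnover rates of
    dissolved acetate from hydrogen isotope disequilibrium with ambient
    water. Fits first-order H-exchange rate constants from incubation time
    series, regresses them against temperature (Arrhenius) and extrapolates
    equilibration times with uncertainty; evaluates temperature-dependent
    equilibrium isotope effects including brine salt-effect and Ca-acetate
    complexation corrections; converts field delta-2H/delta-13C observations
    into disequilibrium calls, residence-time bounds and minimum turnover
    rates; derives activity-corrected Gibbs energies, metabolic power
    densities and supportable cell densities for acetotrophic metabolisms;
    and models radiolytic acetate production from rock U/Th/K content. A
    seeded synthetic-data generator and a command-line pipeline make every
    stage testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
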