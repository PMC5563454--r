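{
  "version": "1.0",
  "reference_an": 121412,
  "note": "Exemplar genetic-architecture parameter sets for inherited conditions, with the maximum tolerated allele count each implies in a reference sample of 121,412 chromosomes at one-sided 95% confidence. Dominant allelic contributions are the upper 95% Wald bound of the most common causal variant's case frequency; cardiovascular penetrance is modelled at 0.5.",
  "diseases": {
    "HCM": {
      "label": "Hypertrophic cardiomyopathy",
      "inheritance": "dominant",
      "prevalence": "1/500",
      "max_allelic_contribution": 0.02,
      "penetrance": 0.5,
      "expected_max_credible_af": 4e-05,
      "expected_max_tolerated_ac": 9,
      "commonest_variant": {"label": "MYBPC3:c.1504C>T", "carriers": 104, "total": 6179, "unit": "cases"}
    },
    "DCM": {
      "label": "Dilated cardiomyopathy",
      "inheritance": "dominant",
      "prevalence": "1/250",
      "max_allelic_contribution": 0.021,
      "penetrance": 0.5,
      "expected_max_credible_af": 8.4e-05,
      "expected_max_tolerated_ac": 16,
      "commonest_variant": {"label": "TNNT2:c.629_631delAGA", "carriers": 18, "total": 1254, "unit": "cases"}
    },
    "ARVC": {
      "label": "Arrhythmogenic right ventricular cardiomyopathy",
      "inheritance": "dominant",
      "prevalence": "1/1000",
      "max_allelic_contribution": 0.092,
      "penetrance": 0.5,
      "expected_max_credible_af": 9.2e-05,
      "expected_max_tolerated_ac": 17,
      "commonest_variant": {"label": "PKP2:c.2146-1G>C", "carriers": 24, "total": 361, "unit": "cases"}
    },
    "LQTS": {
      "label": "Long QT syndrome",
      "inheritance": "dominant",
      "prevalence": "1/2000",
      "max_allelic_contribution": 0.016,
      "penetrance": 0.5,
      "expected_max_credible_af": 8.0e-06,
      "expected_max_tolerated_ac": 3,
      "commonest_variant": {"label": "KCNQ1:c.797T>C", "carriers": 30, "total": 2500, "unit": "cases"}
    },
    "Brugada": {
      "label": "Brugada syndrome",
      "inheritance": "dominant",
      "prevalence": "1/1000",
      "max_allelic_contribution": 0.010,
      "penetrance": 0.5,
      "expected_max_credible_af": 1.0e-05,
      "expected_max_tolerated_ac": 3,
      "commonest_variant": {"label": "SCN5A:c.5350G>A", "carriers": 14, "total": 2111, "unit": "cases"}
    },
    "Marfan": {
      "label": "Marfan syndrome",
      "inheritance": "dominant",
      "prevalence": "1/3000",
      "max_allelic_contribution": 0.015,
      "penetrance": 0.5,
      "expected_max_credible_af": 5.0e-06,
      "expected_max_tolerated_ac": 2
    },
    "Noonan": {
      "label": "Noonan syndrome",
      "inheritance": "dominant",
      "prevalence": "1/1000",
      "max_allelic_contribution": 0.10,
      "penetrance": 0.5,
      "expected_max_credible_af": 1.0e-04,
      "expected_max_tolerated_ac": 18
    },
    "CPVT": {
      "label": "Catecholaminergic polymorphic ventricular tachycardia",
      "inheritance": "dominant",
      "prevalence": "1/10000",
      "max_allelic_contribution": 0.10,
      "penetrance": 0.5,
      "expected_max_credible_af": 1.0e-05,
      "expected_max_tolerated_ac": 3
    },
    "Ehlers-Danlos": {
      "label": "Classic Ehlers-Danlos syndrome",
      "inheritance": "dominant",
      "prevalence": "1/20000",
      "max_allelic_contribution": 0.40,
      "penetrance": 0.5,
      "expected_max_credible_af": 2.0e-05,
      "expected_max_tolerated_ac": 5
    },
    "PCD": {
      "label": "Primary ciliary dyskinesia",
      "inheritance": "recessive",
      "prevalence": "1/10000",
      "max_allelic_contribution": 0.57,
      "max_genetic_contribution": 0.09,
      "penetrance": 0.5,
      "expected_max_credible_af": 2.418e-03,
      "expected_max_tolerated_ac": 322,
      "commonest_variant": {"label": "DNAI1:IVS1+2_3insT", "carriers": 17, "total": 358, "unit": "alleles"}
    }
  }
}
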