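{
  "version": "1.0",
  "comment": "Bundled tracer-specific linear conversions. Coefficients are stored exactly as published (4 decimals). amyloid_CL maps tracer SUVr (whole-cerebellum reference) to Centiloid; tau_CTRz maps tracer SUVr (cerebellar-GM reference) to CenTauRz over the meta-temporal mask; tau_SUVr_CTR holds the FTP pipeline-harmonization map SUVr_CTR = (SUVr - a) / b. level1_anchors holds the PiB two-point calibration group means (young CN A- and AD dementia).",
  "level1_anchors": { "PiB": { "m_ycn": 0.9659, "m_ad": 1.8972 } },
  "amyloid_CL": {
    "PiB": { "slope": 107.3768, "intercept": -103.7152, "r2": null },
    "FBP": { "slope": 194.8721, "intercept": -191.8315, "r2": 0.92 },
    "FBB": { "slope": 165.2828, "intercept": -158.0409, "r2": 0.97 },
    "FTM": { "slope": 141.1563, "intercept": -128.3451, "r2": 0.95 },
    "NAV": { "slope": 104.8498, "intercept": -102.6445, "r2": 0.99 }
  },
  "tau_CTRz": {
    "FTP":  { "slope": 16.9370, "intercept": -19.1334, "r2": 0.98 },
    "RO":   { "slope": 17.2116, "intercept": -20.0144, "r2": null },
    "MK":   { "slope": 12.2417, "intercept": -12.7801, "r2": null },
    "GTP":  { "slope": 12.5556, "intercept": -13.8899, "r2": null },
    "PBB3": { "slope": 15.4067, "intercept": -14.6334, "r2": null },
    "PI":   { "slope": 10.1753, "intercept": -11.5909, "r2": null }
  },
  "tau_SUVr_CTR": {
    "FTP": { "a": 0.2222, "b": 0.7646 }
  }
}
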