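"taxon_id","display_name","group","in_dc_ratio","notes"
"Arcella vulgaris","Arcella vulgaris","other","false",""
"Centropyxis aculeata ""aculeata""","Centropyxis aculeata ""aculeata""","centropyxid","false",""
"Centropyxis aculeata ""discoides""","Centropyxis aculeata ""discoides""","centropyxid","false",""
"Centropyxis constricta ""aerophila""","Centropyxis constricta ""aerophila""","centropyxid","false",""
"Centropyxis constricta ""constricta""","Centropyxis constricta ""constricta""","centropyxid","false",""
"Centropyxis constricta ""spinosa""","Centropyxis constricta ""spinosa""","centropyxid","false",""
"Centropyxis pontigulasiformis","Centropyxis pontigulasiformis","centropyxid","false",""
"Cucurbitella tricuspis","Cucurbitella tricuspis","difflugiid","false","planktic eutrophication indicator; excluded from stress ratio"
"Difflugia bidens","Difflugia bidens","difflugiid","true",""
"Difflugia urceolata ""urceolata""","Difflugia urceolata ""urceolata""","difflugiid","true",""
"Difflugia urceolata ""elongata""","Difflugia urceolata ""elongata""","difflugiid","true",""
"Difflugia urens","Difflugia urens","difflugiid","true",""
"Lesquereusia spiralis","Lesquereusia spiralis","difflugiid","true",""
"Lagenodifflugia vas","Lagenodifflugia vas","difflugiid","true",""
"Pontigulasia compressa","Pontigulasia compressa","difflugiid","true",""
"Difflugia glans ""magna""","Difflugia glans ""magna""","difflugiid","true",""
"Difflugia glans ""distenda""","Difflugia glans ""distenda""","difflugiid","true",""
"Medilous corona","Medilous corona","difflugiid","true",""
"Difflugia oblonga ""oblonga""","Difflugia oblonga ""oblonga""","difflugiid","true",""
"Difflugia oblonga ""spinosa""","Difflugia oblonga ""spinosa""","difflugiid","true",""
"Difflugia oblonga ""lanceolata""","Difflugia oblonga ""lanceolata""","difflugiid","true",""
"Difflugia oblonga ""tenuis""","Difflugia oblonga ""tenuis""","difflugiid","true",""
"Difflugia oblonga ""glans""","Difflugia oblonga ""glans""","difflugiid","true",""
"Difflugia oblonga ""triangularis""","Difflugia oblonga ""triangularis""","difflugiid","true",""
"Difflugia oblonga ""linearis""","Difflugia oblonga ""linearis""","difflugiid","true",""
"Difflugia protaeiformis ""protaeiformis""","Difflugia protaeiformis ""protaeiformis""","difflugiid","true",""
"Difflugia protaeiformis ""claviformis""","Difflugia protaeiformis ""claviformis""","difflugiid","true",""
"Difflugia protaeiformis ""curvicaulis""","Difflugia protaeiformis ""curvicaulis""","difflugiid","true",""
"Difflugia protaeiformis ""amphoralis""","Difflugia protaeiformis ""amphoralis""","difflugiid","true",""
"Difflugia protaeiformis ""acuminata""","Difflugia protaeiformis ""acuminata""","difflugiid","true",""
"Difflugia protaeiformis ""scapellum""","Difflugia protaeiformis ""scapellum""","difflugiid","true",""
"Conicocassis potigulasiformis","Conicocassis potigulasiformis","difflugiid","true",""
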