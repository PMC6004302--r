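sample,depth_top,depth_bottom,Arcella vulgaris,"Centropyxis aculeata ""aculeata""","Centropyxis aculeata ""discoides""","Centropyxis constricta ""aerophila""","Centropyxis constricta ""constricta""","Centropyxis constricta ""spinosa""",Centropyxis pontigulasiformis,Cucurbitella tricuspis,Difflugia bidens,"Difflugia urceolata ""urceolata""","Difflugia urceolata ""elongata""",Difflugia urens,Lesquereusia spiralis,Lagenodifflugia vas,Pontigulasia compressa,"Difflugia glans ""magna""","Difflugia glans ""distenda""",Medilous corona,"Difflugia oblonga ""oblonga""","Difflugia oblonga ""spinosa""","Difflugia oblonga ""lanceolata""","Difflugia oblonga ""tenuis""","Difflugia oblonga ""glans""","Difflugia oblonga ""triangularis""","Difflugia oblonga ""linearis""","Difflugia protaeiformis ""protaeiformis""","Difflugia protaeiformis ""claviformis""","Difflugia protaeiformis ""curvicaulis""","Difflugia protaeiformis ""amphoralis""","Difflugia protaeiformis ""acuminata""","Difflugia protaeiformis ""scapellum""",Conicocassis potigulasiformis
FL1,0,1,0.00,0.01,0.01,0.15,0.04,0.00,0.00,0.19,0.00,0.00,0.00,0.01,0.02,0.03,0.01,0.00,0.00,0.04,0.10,0.15,0.00,0.03,0.04,0.00,0.00,0.00,0.00,0.00,0.13,0.01,0.00,0.00
FL2,1,2,0.00,0.03,0.03,0.08,0.02,0.00,0.00,0.39,0.00,0.00,0.00,0.00,0.02,0.00,0.00,0.00,0.01,0.02,0.11,0.11,0.00,0.07,0.01,0.00,0.00,0.01,0.01,0.02,0.03,0.02,0.00,0.00
FL3,2,3,0.00,0.01,0.04,0.23,0.05,0.01,0.00,0.18,0.01,0.00,0.01,0.00,0.01,0.01,0.01,0.00,0.00,0.02,0.07,0.11,0.00,0.04,0.01,0.00,0.00,0.01,0.09,0.02,0.00,0.04,0.00,0.00
FL4,3,4,0.00,0.04,0.04,0.10,0.04,0.00,0.00,0.22,0.01,0.00,0.01,0.01,0.03,0.01,0.00,0.00,0.01,0.03,0.10,0.19,0.00,0.00,0.00,0.01,0.00,0.00,0.01,0.00,0.09,0.02,0.00,0.00
FL5,4,5,0.00,0.03,0.05,0.13,0.07,0.00,0.01,0.15,0.03,0.00,0.01,0.05,0.00,0.01,0.00,0.01,0.01,0.00,0.03,0.02,0.00,0.08,0.12,0.01,0.00,0.00,0.07,0.01,0.09,0.01,0.00,0.00
FL6,5,6,0.00,0.05,0.03,0.13,0.07,0.00,0.00,0.19,0.01,0.00,0.07,0.00,0.02,0.00,0.00,0.00,0.00,0.01,0.04,0.26,0.00,0.03,0.01,0.01,0.01,0.01,0.01,0.00,0.01,0.00,0.00,0.00
FL7,6,7,0.02,0.13,0.18,0.23,0.10,0.00,0.00,0.18,0.00,0.00,0.02,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0.04,0.07,0.00,0.01,0.00,0.00,0.00,0.01,0.01,0.00,0.00,0.00,0.00,0.00
FL8,7,8,0.00,0.14,0.14,0.23,0.14,0.02,0.00,0.10,0.00,0.00,0.00,0.00,0.04,0.01,0.01,0.01,0.00,0.01,0.04,0.02,0.00,0.01,0.06,0.00,0.00,0.01,0.00,0.00,0.02,0.01,0.00,0.01
FL9,8,9,0.00,0.14,0.12,0.27,0.14,0.02,0.00,0.03,0.00,0.01,0.01,0.03,0.01,0.01,0.00,0.00,0.00,0.02,0.01,0.01,0.00,0.00,0.07,0.00,0.00,0.01,0.01,0.01,0.06,0.01,0.00,0.00
FL10,9,10,0.01,0.10,0.06,0.17,0.19,0.01,0.00,0.18,0.00,0.00,0.04,0.00,0.00,0.00,0.00,0.00,0.00,0.04,0.10,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0.08,0.00,0.00,0.00
FL11,10,11,0.01,0.17,0.10,0.17,0.16,0.00,0.00,0.06,0.01,0.01,0.01,0.02,0.02,0.01,0.00,0.00,0.00,0.01,0.05,0.00,0.00,0.00,0.04,0.00,0.00,0.01,0.06,0.01,0.06,0.02,0.00,0.00
FL12,11,12,0.01,0.07,0.07,0.26,0.23,0.00,0.00,0.05,0.03,0.01,0.02,0.00,0.01,0.01,0.00,0.00,0.00,0.01,0.07,0.00,0.00,0.01,0.09,0.00,0.00,0.00,0.03,0.00,0.04,0.00,0.00,0.00
FL13,12,13,0.00,0.07,0.06,0.27,0.28,0.00,0.00,0.04,0.00,0.03,0.01,0.00,0.01,0.00,0.00,0.00,0.00,0.00,0.05,0.00,0.00,0.01,0.09,0.00,0.00,0.01,0.04,0.00,0.04,0.00,0.00,0.00
FL14,13,14,0.00,0.07,0.05,0.21,0.18,0.00,0.00,0.04,0.00,0.02,0.04,0.01,0.01,0.01,0.01,0.00,0.00,0.01,0.09,0.00,0.00,0.01,0.09,0.00,0.00,0.01,0.06,0.00,0.10,0.00,0.00,0.00
FL15,14,15,0.00,0.07,0.06,0.29,0.16,0.01,0.00,0.03,0.01,0.00,0.02,0.02,0.00,0.00,0.00,0.00,0.02,0.00,0.05,0.01,0.02,0.03,0.03,0.00,0.01,0.01,0.07,0.01,0.06,0.01,0.00,0.00
FL16,15,16,0.00,0.03,0.05,0.20,0.15,0.02,0.00,0.04,0.01,0.03,0.04,0.02,0.01,0.00,0.00,0.00,0.00,0.01,0.09,0.03,0.01,0.02,0.06,0.00,0.00,0.01,0.11,0.01,0.07,0.00,0.00,0.00
FL17,16,17,0.00,0.11,0.09,0.11,0.04,0.02,0.00,0.01,0.00,0.01,0.03,0.03,0.00,0.02,0.01,0.00,0.01,0.00,0.20,0.06,0.00,0.05,0.03,0.00,0.00,0.03,0.03,0.01,0.11,0.01,0.00,0.00
FL18,17,18,0.00,0.06,0.09,0.10,0.06,0.01,0.00,0.01,0.00,0.00,0.07,0.02,0.00,0.02,0.00,0.00,0.03,0.00,0.19,0.02,0.00,0.02,0.03,0.00,0.00,0.04,0.07,0.01,0.14,0.02,0.00,0.00
FL19,18,19,0.00,0.14,0.05,0.14,0.08,0.01,0.00,0.01,0.01,0.01,0.03,0.00,0.00,0.02,0.00,0.00,0.03,0.00,0.22,0.01,0.00,0.01,0.05,0.00,0.00,0.05,0.04,0.00,0.09,0.00,0.00,0.00
FL20,19,20,0.00,0.13,0.03,0.07,0.09,0.01,0.00,0.00,0.00,0.00,0.05,0.02,0.01,0.01,0.01,0.00,0.01,0.00,0.25,0.01,0.00,0.03,0.05,0.00,0.01,0.01,0.06,0.00,0.16,0.00,0.00,0.00
FL21,20,21,0.00,0.06,0.01,0.03,0.08,0.01,0.00,0.02,0.00,0.01,0.04,0.05,0.00,0.03,0.01,0.00,0.05,0.00,0.05,0.01,0.00,0.21,0.03,0.00,0.00,0.04,0.01,0.00,0.23,0.02,0.00,0.00
FL22,21,22,0.00,0.03,0.02,0.03,0.07,0.00,0.00,0.01,0.00,0.01,0.03,0.03,0.00,0.04,0.00,0.00,0.01,0.00,0.11,0.03,0.00,0.16,0.05,0.00,0.00,0.01,0.05,0.00,0.30,0.01,0.00,0.00
FL23,22,23,0.00,0.00,0.01,0.03,0.06,0.00,0.00,0.03,0.01,0.00,0.02,0.00,0.01,0.03,0.00,0.00,0.00,0.03,0.28,0.07,0.00,0.03,0.00,0.00,0.01,0.01,0.05,0.01,0.28,0.00,0.00,0.00
FL24,23,24,0.00,0.01,0.00,0.04,0.04,0.00,0.00,0.01,0.01,0.02,0.05,0.01,0.00,0.05,0.01,0.00,0.00,0.04,0.18,0.13,0.00,0.05,0.00,0.00,0.01,0.03,0.03,0.01,0.28,0.00,0.00,0.00
FL25,24,25,0.00,0.00,0.00,0.02,0.05,0.01,0.00,0.05,0.01,0.01,0.03,0.00,0.00,0.03,0.01,0.00,0.00,0.01,0.23,0.11,0.00,0.03,0.05,0.00,0.01,0.00,0.05,0.01,0.31,0.00,0.00,0.00
FL26,25,26,0.00,0.02,0.00,0.05,0.05,0.01,0.00,0.01,0.00,0.00,0.03,0.00,0.00,0.04,0.00,0.00,0.00,0.01,0.17,0.15,0.01,0.03,0.01,0.00,0.01,0.02,0.09,0.02,0.25,0.01,0.00,0.00
FL27,26,27,0.00,0.07,0.03,0.07,0.04,0.01,0.00,0.01,0.00,0.01,0.05,0.01,0.00,0.03,0.00,0.00,0.00,0.01,0.17,0.11,0.01,0.03,0.04,0.00,0.00,0.00,0.02,0.02,0.26,0.00,0.00,0.00
FL28,27,28,0.00,0.08,0.06,0.01,0.07,0.01,0.00,0.01,0.01,0.03,0.05,0.01,0.00,0.01,0.01,0.01,0.00,0.01,0.13,0.14,0.01,0.02,0.02,0.00,0.00,0.01,0.04,0.01,0.23,0.01,0.00,0.00
FL29,28,29,0.01,0.06,0.02,0.02,0.07,0.01,0.00,0.03,0.00,0.01,0.00,0.03,0.00,0.02,0.02,0.00,0.00,0.00,0.27,0.11,0.00,0.02,0.03,0.00,0.00,0.02,0.06,0.00,0.19,0.00,0.00,0.00
FL30,29,30,0.01,0.09,0.02,0.01,0.05,0.00,0.00,0.03,0.00,0.05,0.03,0.00,0.00,0.01,0.01,0.00,0.00,0.01,0.24,0.09,0.00,0.01,0.02,0.00,0.00,0.05,0.02,0.00,0.26,0.01,0.00,0.00
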