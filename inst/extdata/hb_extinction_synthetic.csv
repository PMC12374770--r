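wavelength_nm,eps_hbo2,eps_hb
600,3200.0,14677.2
610,1506.0,9443.8
620,942.0,6509.6
630,610.0,5148.8
640,442.0,4345.2
650,368.0,3750.1
660,319.6,3226.6
670,294.0,2795.1
680,277.6,2407.9
690,276.0,2051.9
700,290.0,1794.3
710,314.0,1540.5
720,348.0,1244.8
730,390.0,1102.2
740,446.0,1115.9
750,518.0,1405.2
760,586.0,1548.5
770,650.0,1311.9
780,710.0,1075.4
790,774.0,890.8
800,816.0,761.7
810,864.0,717.1
820,916.0,693.8
830,974.0,693.0
840,1022.0,692.4
850,1058.0,691.3
860,1086.0,691.2
870,1118.0,694.3
880,1154.0,707.0
890,1178.0,724.0
900,1198.0,749.7
910,1218.0,768.0
920,1232.0,774.0
930,1238.0,760.0
940,1214.0,734.0
950,1204.0,710.0
960,1192.0,680.0
970,1180.0,648.0
980,1166.0,616.0
990,1130.0,580.0
1000,1096.0,548.0
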