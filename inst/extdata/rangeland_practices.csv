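operation_id,location,ivermectin_applications_per_year,ivermectin_applied_during_grazing,stocking_density_au_per_ha,rotation_frequency_days,rest_period_days,code_ivermectin,code_stocking_density,code_rotation_frequency,code_rest_period,composite_printed,erratum
ranch01,"Bruce, SD",1,no,3,45,0,1,0,0,0,1,FALSE
ranch02,"Castlewood, SD",1,no,12,20,60,1,2,1,2,6,FALSE
ranch03,"Clear Lake, SD",0,no,12,7,60,2,2,2,2,8,FALSE
ranch04,"Estelline, SD",1,no,7.5,20,60,1,1,1,2,5,FALSE
ranch05,"Estelline, SD",3,no,7.5,45,0,0,1,0,0,1,FALSE
ranch06,"Flandreau, SD",3,no,3,45,0,0,0,0,0,0,FALSE
ranch07,"Gary, SD",0,no,12,7,60,2,2,2,2,8,FALSE
ranch08,"Goodwin, SD",0,no,12,7,60,2,2,2,2,8,FALSE
ranch09,"Madison, SD",3,no,7.5,20,60,0,1,1,2,4,FALSE
ranch10,"Milbank, SD",1,no,7.5,20,60,1,1,1,2,5,FALSE
ranch11,"Milbank, SD",3,no,3,45,60,0,0,0,2,2,FALSE
ranch12,"Sioux Falls, SD",0,no,12,7,60,2,2,2,2,8,FALSE
ranch13,"Summit, SD",1,no,7.5,20,60,1,1,1,2,5,FALSE
ranch14,"Thomas, SD",1,no,7.5,7,60,1,1,2,2,6,FALSE
ranch15,"Twin Brooks, SD",0,no,12,20,60,2,2,1,2,7,FALSE
ranch16,"Volga, SD",3,no,3,45,0,0,0,0,0,0,FALSE
ranch17,"Hayti, SD",3,no,3,45,0,0,0,0,0,0,FALSE
ranch18,"Hayti, SD",3,no,3,45,0,0,0,0,0,0,FALSE
ranch19,"Strandburg, SD",3,no,3,45,0,0,0,0,0,0,FALSE
ranch20,"Estelline, SD",3,no,3,45,0,0,0,0,0,0,FALSE
ranch21,"Watertown, SD",1,no,12,7,60,1,2,2,2,7,FALSE
ranch22,"Hayti, SD",1,no,7.5,7,60,1,1,2,2,6,FALSE
ranch23,"Estelline, SD",0,no,7.5,7,60,2,1,2,2,7,FALSE
ranch24,"Gary, SD",0,no,7.5,7,60,2,1,2,2,7,FALSE
ranch25,"Goodwin, SD",1,no,7.5,7,60,1,1,2,2,6,FALSE
ranch26,"Tuttle, ND",1,no,3,45,0,1,0,0,0,1,FALSE
ranch27,"Tuttle, ND",3,no,3,45,0,0,0,0,0,0,FALSE
ranch28,"Wing, ND",3,no,3,45,0,0,0,0,0,0,FALSE
ranch29,"Moffit, ND",1,no,3,45,0,1,0,0,0,1,FALSE
ranch30,"Fort Rice, ND",0,no,12,7,60,2,2,2,2,8,FALSE
ranch31,"ND7; Wing, ND",0,no,7.5,7,60,2,1,2,2,7,FALSE
ranch32,"Bismarck, ND",0,no,12,7,60,2,2,2,2,8,FALSE
ranch33,"Wing, ND",0,no,12,7,60,2,2,2,2,8,FALSE
ranch34,"Moffit, ND",0,no,12,7,60,2,2,2,2,8,FALSE
ranch35,"Summit, SD",3,no,3,7,60,0,0,2,2,4,FALSE
ranch36,"Summit, SD",3,no,3,45,0,0,0,0,0,0,FALSE
ranch37,"Milbank, SD",0,no,7.5,20,60,2,1,1,2,6,FALSE
ranch38,"Milbank, SD",3,no,3,45,0,0,0,0,0,0,FALSE
ranch39,"Watertown, SD",0,no,12,7,60,2,2,2,2,8,FALSE
ranch40,"Castlewood, SD",3,no,3,45,0,0,0,0,0,0,FALSE
ranch41,"Summit, SD",0,no,3,7,60,2,0,2,2,6,FALSE
ranch42,"Milbank, SD",3,no,3,45,0,0,0,0,0,0,FALSE
ranch43,"Castlewood, SD",0,no,12,7,60,2,2,2,2,8,FALSE
ranch44,"Castlewood, SD",3,no,3,45,60,0,0,0,2,2,TRUE
ranch45,"Sheldon, ND",3,no,7.5,7,60,0,1,2,2,5,FALSE
ranch46,"Sheldon, ND",3,no,3,45,0,0,0,0,0,0,FALSE
ranch47,"Napoleon, ND",3,no,12,7,60,0,2,2,2,6,FALSE
ranch48,"Napoleon, ND",3,no,3,45,0,0,0,0,0,0,FALSE
ranch49,"Ellendale, ND",0,no,12,7,60,2,2,2,2,8,FALSE
ranch50,"Forbes, ND",1,no,3,20,60,1,0,1,2,4,FALSE
ranch51,"Forbes, ND",0,no,12,7,60,2,2,2,2,8,FALSE
ranch52,"Berlin, ND",3,no,7.5,20,0,0,1,1,0,2,FALSE
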